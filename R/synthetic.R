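#' Configuration for the synthetic colony generator
#'
#' Defaults emulate a starved ~50-worker colony observed for 90 minutes at
#' 1-minute scan resolution: roughly a fifth of the workers are foragers,
#' ants join the exchange network with exponentially distributed latencies
#' (mean 35 min), and post-onset donation rates are gamma-distributed across
#' individuals (finite `shape_give` gives negative-binomial, overdispersed,
#' per-ant counts; `shape_give = Inf` is the Poisson-homogeneous null).
#'
#' @param n_ants Colony size.
#' @param forager_fraction Fraction of foragers.
#' @param t_end_min Trial length in minutes (1-min scans).
#' @param onset_mean_min Mean of the exponential first-event latency (min).
#' @param p_active Named per-caste probability that an ant ever joins the
#'   exchange network; ants that do not stay naive for the whole trial
#'   (roughly half the workers, mostly non-foragers, never exchange).
#' @param mean_rate_give Named per-caste mean post-onset donation rates
#'   (events per minute).
#' @param shape_give Gamma shape of the per-ant donation-rate distribution
#'   (`Inf` = homogeneous).
#' @param shape_receive Gamma shape of per-ant receiver-attractiveness
#'   weights (`Inf` = uniform receiver choice).
#' @param redistribution_ramp Exponent shaping when an ant's repeat
#'   donations fall inside its post-onset window: 0 = uniform, larger
#'   values weight them toward the end of the trial (repeat redistribution
#'   builds up as crops fill; the spatial shift of exchanges away from the
#'   entrance after the first half hour reflects the same late secondary
#'   phase). Repeat-event times are `o + (T - o) * U^(1/(1 + ramp))`.
#' @param p_donor_at_onset Named per-caste probability that an ant's first
#'   event is a donation (otherwise it first receives).
#' @param donor_weight Named per-caste weights for choosing which earlier
#'   participant donates to a newly joining receiver.
#' @param p_duration Probabilities of event durations 1, 2, 3 minutes.
#' @param partner_choice `"engaged"` (default: partners drawn among ants
#'   already in the network, a ladenness proxy) or `"uniform"` (every event
#'   assigned to a uniformly random ordered pair — the caste-blind null
#'   world of the Full Random reference model).
#' @param first_visit_mean_s Mean first feeding-visit time of foragers (s).
#' @param visit_rate_per_min Rate of subsequent forager visits (per min).
#' @param visit_duration_s Range of visit durations (s); the lower bound is
#'   above the 5-s forager threshold so true castes are recoverable.
#' @param nf_cluster_sd_mm Spread of the non-forager home cluster (mm).
#' @param f_home_sd_mm Spread of forager home positions (mm).
#' @param event_noise_sd_mm Scatter of event positions around their
#'   expected location (mm).
#' @param receiver_anchor Weight of the receiver's home in the expected
#'   event position (the receiver is the more stationary partner; the donor
#'   travels to it).
#' @param entrance_bias Initial pull of forager-donated event positions
#'   toward the nest entrance (0-1), decaying linearly to 0 at `t_end_min`.
#' @param geometry A [nest_geometry()].
#' @param seed Integer seed; the whole colony is deterministic given it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_ants = 53,
                              forager_fraction = 0.23,
                              t_end_min = 90,
                              onset_mean_min = 35,
                              p_active = c(F = 0.95, NF = 0.55),
                              mean_rate_give = c(F = 0.06, NF = 0.005),
                              shape_give = 1,
                              shape_receive = 1,
                              redistribution_ramp = 2,
                              p_donor_at_onset = c(F = 0.95, NF = 0.55),
                              donor_weight = c(F = 4, NF = 1),
                              p_duration = c(0.86, 0.12, 0.02),
                              partner_choice = c("engaged", "uniform"),
                              first_visit_mean_s = 300,
                              visit_rate_per_min = 0.05,
                              visit_duration_s = c(6, 60),
                              nf_cluster_sd_mm = 8,
                              f_home_sd_mm = 22,
                              event_noise_sd_mm = 12,
                              receiver_anchor = 0.65,
                              entrance_bias = 0.35,
                              geometry = nest_geometry(),
                              seed = 1) {
  partner_choice <- match.arg(partner_choice)
  stopifnot(n_ants >= 3, forager_fraction > 0, forager_fraction < 1,
            t_end_min >= 2, onset_mean_min > 0,
            all(p_active > 0 & p_active <= 1),
            all(mean_rate_give >= 0), shape_give > 0, shape_receive > 0,
            all(p_donor_at_onset >= 0 & p_donor_at_onset <= 1),
            all(donor_weight > 0), redistribution_ramp >= 0,
            abs(sum(p_duration) - 1) < 1e-9,
            entrance_bias >= 0, entrance_bias <= 1,
            receiver_anchor >= 0, receiver_anchor <= 1,
            visit_duration_s[1] > 5)
  structure(as.list(environment()), class = "simulation_config")
}

truncnorm2 <- function(n, mx, my, sd, geometry) {
  # isotropic Gaussian scatter truncated to the nest by resampling
  x <- stats::rnorm(n, mx, sd)
  y <- stats::rnorm(n, my, sd)
  for (i in seq_len(50)) {
    bad <- x < 0 | x > geometry$width_mm | y < 0 | y > geometry$height_mm
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mx[bad], sd)
    y[bad] <- stats::rnorm(sum(bad), my[bad], sd)
  }
  x <- pmin(pmax(x, 0), geometry$width_mm)
  y <- pmin(pmax(y, 0), geometry$height_mm)
  cbind(x, y)
}

#' Simulate a synthetic colony
#'
#' Generates a full synthetic data set — scan table, feeding visits,
#' per-window ant positions, roster, true castes — with the statistical
#' structure the analysis pipeline assumes, and keeps every generating
#' parameter for recovery tests (see [ground_truth()]).
#'
#' The generative model: each ant joins the exchange network after an
#' exponential latency (its onset); its first event is a donation or a
#' receipt (caste-dependent probability), the partner being drawn among
#' earlier joiners. After onset, each ant initiates further donations as a
#' Poisson process with a personal gamma-distributed rate; receivers are
#' drawn among ants already in the network, weighted by personal
#' attractiveness. Foragers reload at the food source through feeding
#' visits. Event positions scatter around the midpoint of the partners'
#' home locations — non-foragers share a tight cluster away from the
#' entrance, forager homes are dispersed — and forager donations are pulled
#' toward the entrance early in the trial, a pull that decays linearly with
#' time. Events are discretised to 1-min scans, multi-minute events
#' appearing as consecutive-scan runs; the canonical event list is what
#' [merge_consecutive_scans()] recovers from the emitted scan table, so the
#' data round-trip exactly through the parsers.
#'
#' @param config A [simulation_config()].
#' @return List of class `simulated_colony` with elements `scans`, `events`
#'   (canonical merged events), `visits`, `positions` (per-window ant
#'   snapshots), `roster`, `castes` (true castes), `geometry`, `config`,
#'   `truth`.
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  geom <- config$geometry
  n <- config$n_ants
  roster <- sprintf("a%02d", seq_len(n))
  n_f <- max(1L, round(n * config$forager_fraction))
  caste <- c(rep("F", n_f), rep("NF", n - n_f))
  castes <- data.frame(ant = roster, caste = caste, stringsAsFactors = FALSE)

  t_end <- config$t_end_min
  onset <- stats::rexp(n, rate = 1 / config$onset_mean_min)
  joins <- stats::runif(n) < config$p_active[caste]
  onset[!joins] <- Inf
  active <- onset < t_end
  if (sum(active) < 2) stop("configuration yields fewer than two active ants")

  rate_mean <- config$mean_rate_give[caste]
  g <- if (is.finite(config$shape_give)) {
    stats::rgamma(n, shape = config$shape_give,
                  scale = rate_mean / config$shape_give)
  } else rate_mean
  w_recv <- if (is.finite(config$shape_receive)) {
    stats::rgamma(n, shape = config$shape_receive,
                  scale = 1 / config$shape_receive)
  } else rep(1, n)
  d_weight <- config$donor_weight[caste]

  # --- event stream -------------------------------------------------------
  ord <- order(onset)
  act_ord <- ord[onset[ord] < t_end]
  ev_time <- numeric(0)
  ev_donor <- integer(0)
  ev_recv <- integer(0)

  # onset events: each joiner pairs with an earlier joiner (the very first
  # ant joins as the counterpart of the second onset)
  for (k in seq_along(act_ord)[-1]) {
    i <- act_ord[k]
    earlier <- act_ord[seq_len(k - 1)]
    is_donor <- stats::runif(1) < config$p_donor_at_onset[caste[i]]
    if (is_donor) {
      partner <- if (length(earlier) == 1) earlier else
        sample(earlier, 1, prob = w_recv[earlier])
      ev_donor <- c(ev_donor, i); ev_recv <- c(ev_recv, partner)
    } else {
      partner <- if (length(earlier) == 1) earlier else
        sample(earlier, 1, prob = d_weight[earlier])
      ev_donor <- c(ev_donor, partner); ev_recv <- c(ev_recv, i)
    }
    ev_time <- c(ev_time, onset[i])
  }

  # post-onset donations: personal Poisson process over the remaining time
  for (i in act_ord) {
    n_extra <- stats::rpois(1, g[i] * (t_end - onset[i]))
    if (n_extra == 0) next
    u <- stats::runif(n_extra)^(1 / (1 + config$redistribution_ramp))
    times <- onset[i] + (t_end - onset[i]) * u
    for (t in times) {
      cand <- act_ord[onset[act_ord] <= t]
      cand <- setdiff(cand, i)
      if (length(cand) == 0) cand <- setdiff(seq_len(n), i)
      r <- if (length(cand) == 1) cand else sample(cand, 1, prob = w_recv[cand])
      ev_time <- c(ev_time, t)
      ev_donor <- c(ev_donor, i)
      ev_recv <- c(ev_recv, r)
    }
  }
  if (length(ev_time) == 0) stop("configuration yields zero events")

  if (config$partner_choice == "uniform") {
    m <- length(ev_time)
    ev_donor <- sample.int(n, m, replace = TRUE)
    shift <- sample.int(n - 1L, m, replace = TRUE)
    ev_recv <- (ev_donor + shift - 1L) %% n + 1L
  }

  # --- positions ----------------------------------------------------------
  nf_center <- c(0.68 * geom$width_mm, 0.5 * geom$height_mm)
  home <- matrix(NA_real_, n, 2)
  is_f <- caste == "F"
  home[!is_f, ] <- truncnorm2(sum(!is_f), rep(nf_center[1], sum(!is_f)),
                              rep(nf_center[2], sum(!is_f)),
                              config$nf_cluster_sd_mm, geom)
  home[is_f, ] <- truncnorm2(sum(is_f),
                             rep(0.5 * geom$width_mm, sum(is_f)),
                             rep(0.5 * geom$height_mm, sum(is_f)),
                             config$f_home_sd_mm, geom)

  # the receiver is the more stationary partner: events sit nearer its home
  a <- config$receiver_anchor
  mx <- (1 - a) * home[ev_donor, 1] + a * home[ev_recv, 1]
  my <- (1 - a) * home[ev_donor, 2] + a * home[ev_recv, 2]
  pull <- ifelse(is_f[ev_donor],
                 config$entrance_bias * pmax(0, 1 - ev_time / t_end), 0)
  mx <- (1 - pull) * mx + pull * geom$entrance_mm[1]
  my <- (1 - pull) * my + pull * geom$entrance_mm[2]
  pos <- truncnorm2(length(ev_time), mx, my, config$event_noise_sd_mm, geom)

  # --- discretise to scans ------------------------------------------------
  start_min <- pmin(floor(ev_time), t_end - 1L)
  dur <- sample.int(3L, length(ev_time), replace = TRUE,
                    prob = config$p_duration)
  dur <- pmin(dur, t_end - start_min)
  raw_events <- data.frame(donor = roster[ev_donor],
                           receiver = roster[ev_recv],
                           start_min = as.integer(start_min),
                           duration_min = as.integer(dur),
                           x_mm = pos[, 1], y_mm = pos[, 2],
                           stringsAsFactors = FALSE)
  scans <- events_to_scans(raw_events)
  # same-pair collisions on consecutive minutes merge on parsing; take the
  # merged list as canonical so the data round-trip exactly
  scans <- scans[!duplicated(scans[c("minute", "donor", "receiver")]), ,
                 drop = FALSE]
  rownames(scans) <- NULL
  events <- merge_consecutive_scans(scans)

  # --- feeding visits -----------------------------------------------------
  vrows <- list()
  for (i in which(is_f)) {
    first_v <- stats::rexp(1, 1 / config$first_visit_mean_s)
    n_more <- stats::rpois(1, config$visit_rate_per_min * t_end)
    starts <- sort(c(first_v, stats::runif(n_more, first_v, t_end * 60)))
    durs <- stats::runif(length(starts), config$visit_duration_s[1],
                         config$visit_duration_s[2])
    vrows[[length(vrows) + 1]] <-
      data.frame(ant = roster[i], start_s = starts, duration_s = durs,
                 stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, vrows)
  rownames(visits) <- NULL

  # --- per-window snapshot positions -------------------------------------
  n_win <- ceiling(t_end / 10)
  prow <- lapply(0:(n_win - 1), function(w) {
    p <- truncnorm2(n, home[, 1], home[, 2],
                    ifelse(is_f, config$f_home_sd_mm, config$nf_cluster_sd_mm),
                    geom)
    data.frame(minute = w * 10, ant = roster, x_mm = p[, 1], y_mm = p[, 2],
               stringsAsFactors = FALSE)
  })
  positions <- do.call(rbind, prow)
  rownames(positions) <- NULL

  structure(list(
    scans = scans, events = events, visits = visits, positions = positions,
    roster = roster, castes = castes, geometry = geom, config = config,
    truth = list(onset_mean_min = config$onset_mean_min,
                 onset_min = stats::setNames(onset, roster),
                 rate_give = stats::setNames(g, roster),
                 receive_weight = stats::setNames(w_recv, roster),
                 home_mm = home,
                 forager_fraction = n_f / n,
                 mean_rate_give = config$mean_rate_give)
  ), class = "simulated_colony")
}

#' @export
print.simulated_colony <- function(x, ...) {
  cat(sprintf("simulated colony: %d ants (%d foragers), %d events, %d scans, %d visits\n",
              length(x$roster), sum(x$castes$caste == "F"), nrow(x$events),
              nrow(x$scans), nrow(x$visits)))
  invisible(x)
}

#' Ground-truth parameters of a simulated colony
#'
#' @param colony A `simulated_colony`.
#' @return The generating parameter record: onset mean, per-ant onsets and
#'   donation rates, per-caste mean rates, forager fraction, home positions.
#' @export
ground_truth <- function(colony) {
  stopifnot(inherits(colony, "simulated_colony"))
  colony$truth
}

#' Write a simulated colony to CSV files
#'
#' Emits the scan table, feeding-visit table and roster in the same CSV
#' schemas the readers expect.
#'
#' @param colony A `simulated_colony`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_colony_csv <- function(colony, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scans = file.path(dir, "scans.csv"),
             visits = file.path(dir, "visits.csv"),
             roster = file.path(dir, "roster.csv"))
  utils::write.csv(colony$scans, paths["scans"], row.names = FALSE)
  utils::write.csv(colony$visits, paths["visits"], row.names = FALSE)
  utils::write.csv(data.frame(ant = colony$roster), paths["roster"],
                   row.names = FALSE)
  invisible(paths)
}
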