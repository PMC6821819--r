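#' Run configuration for the analysis pipeline
#'
#' Either point the pipeline at recorded CSV tables (`scan_path`,
#' `visit_path`, `roster_path`) or let it simulate a colony
#' (`simulate = simulation_config(...)`).
#'
#' @param scan_path,visit_path,roster_path Input CSVs (see
#'   [read_scan_table()], [read_feeding_visits()]); ignored when `simulate`
#'   is given.
#' @param simulate Optional [simulation_config()].
#' @param geometry [nest_geometry()].
#' @param n_replicates Reference-model ensemble size (default 1000;
#'   at least 100 for reported p-values).
#' @param seed Master seed for all randomization.
#' @param gini_scope Scope of the Gini vs FR comparison (`"active"`
#'   default).
#' @param out_dir Optional directory; when given, intermediate tables are
#'   exported as CSV.
#' @return List of class `run_config`.
#' @export
run_config <- function(scan_path = NULL, visit_path = NULL,
                       roster_path = NULL, simulate = NULL,
                       geometry = nest_geometry(), n_replicates = 1000,
                       seed = 1, gini_scope = c("active", "all"),
                       out_dir = NULL) {
  gini_scope <- match.arg(gini_scope)
  stopifnot(n_replicates >= 100)
  if (is.null(simulate) &&
      (is.null(scan_path) || is.null(visit_path) || is.null(roster_path))) {
    stop("either supply all three input paths or a simulation config")
  }
  structure(list(scan_path = scan_path, visit_path = visit_path,
                 roster_path = roster_path, simulate = simulate,
                 geometry = geometry, n_replicates = n_replicates,
                 seed = seed, gini_scope = gini_scope, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; a `simulate` block
#' is passed to [simulation_config()] and a `geometry` block to
#' [nest_geometry()]. Named per-caste vectors are written as YAML maps,
#' e.g. `mean_rate_give: {F: 0.06, NF: 0.005}`.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  geometry <- if (is.null(y$geometry)) nest_geometry() else
    do.call(nest_geometry, y$geometry)
  simulate <- if (is.null(y$simulate)) NULL else {
    sim <- y$simulate
    for (f in c("mean_rate_give", "p_donor_at_onset", "donor_weight")) {
      if (!is.null(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
    }
    sim$geometry <- geometry
    do.call(simulation_config, sim)
  }
  args <- y[intersect(names(y), c("scan_path", "visit_path", "roster_path",
                                  "n_replicates", "seed", "gini_scope",
                                  "out_dir"))]
  args$geometry <- geometry
  args$simulate <- simulate
  do.call(run_config, args)
}

#' Load or simulate the input data of one colony
#'
#' @param config A [run_config()].
#' @return List with `scans`, `visits`, `roster`, `castes`, `events`.
#' @export
load_colony_data <- function(config) {
  if (!is.null(config$simulate)) {
    col <- simulate_colony(config$simulate)
    return(list(scans = col$scans, visits = col$visits, roster = col$roster,
                castes = col$castes, events = col$events,
                positions = col$positions))
  }
  roster <- as.character(utils::read.csv(config$roster_path)$ant)
  scans <- read_scan_table(config$scan_path, roster, config$geometry)
  visits <- read_feeding_visits(config$visit_path)
  castes <- assign_castes(visits, roster)
  list(scans = scans, visits = visits, roster = roster, castes = castes,
       events = merge_consecutive_scans(scans), positions = NULL)
}

#' Run the full trophallactic-network analysis
#'
#' Executes event construction, caste classification, network metrics,
#' inequality measures with the Full Random (FR) comparison, temporal
#' spreading with the time-permutation (RP) comparison, dispersion tests,
#' and the spatial analyses, in that order, deterministically for a given
#' seed. Every reported p-value names its test and sidedness.
#'
#' @param config A [run_config()].
#' @return List of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dat <- load_colony_data(config)
  events <- dat$events
  castes <- dat$castes
  roster <- dat$roster
  profiles <- build_profiles(events, dat$visits, castes)
  net <- build_network(events, castes)

  caste_summary <- do.call(rbind, lapply(c("F", "NF"), function(cs) {
    p <- profiles[profiles$caste == cs, , drop = FALSE]
    data.frame(caste = cs, n_ants = nrow(p), n_active = sum(p$active),
               events_given = sum(p$n_given),
               events_received = sum(p$n_received),
               mean_given = mean(p$n_given),
               mean_received = mean(p$n_received),
               mean_balance = mean(p$balance),
               stringsAsFactors = FALSE)
  }))

  metrics <- node_centralities(net)
  efficiency <- global_efficiency(net)
  shares <- pair_type_shares(events, castes)
  pratio <- pair_ratio(events)

  gini_obs <- local({
    x <- profiles$n_total
    if (config$gini_scope == "active") x <- x[x > 0]
    gini_coefficient(x)
  })
  gini_stat <- function(e) {
    counts <- table(factor(c(e$donor, e$receiver), levels = roster))
    x <- as.numeric(counts)
    if (config$gini_scope == "active") x <- x[x > 0]
    gini_coefficient(x)
  }
  fr_gini <- null_distribution(events, roster, "FR", gini_stat,
                               config$n_replicates, config$seed)
  gini_test <- z_test(gini_obs, fr_gini, sidedness = "greater")

  eff_stat <- function(e) global_efficiency(build_network(e, castes))
  fr_eff <- null_distribution(events, roster, "FR", eff_stat,
                              config$n_replicates, config$seed + 1L)
  eff_test <- z_test(efficiency, fr_eff, sidedness = "two")

  fr_pratio <- null_distribution(events, roster, "FR", pair_ratio,
                                 config$n_replicates, config$seed + 2L)
  pratio_test <- z_test(pratio, fr_pratio, sidedness = "two")

  # the joiners-only curve is reported: with a partially inactive colony the
  # whole-colony curve plateaus and a single latency scale is meaningless
  surv <- naive_survival(events, roster, role = "any", scope = "active",
                         t_max = max(events$start_min))
  expfit <- fit_exponential(surv)
  t50_test <- tryCatch(
    spreading_vs_rp(events, roster, role = "any",
                    n_replicates = config$n_replicates,
                    seed = config$seed + 3L),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "z_test_result"))
  quantiles <- do.call(rbind, lapply(c("F", "NF"), function(cs) {
    ids <- castes$ant[castes$caste == cs]
    do.call(rbind, lapply(c("given", "received"), function(role) {
      ft <- first_event_times(events, ids, role)
      q <- spread_quantiles(ft, reference_size = sum(!is.na(ft)))
      data.frame(caste = cs, role = role, T50 = q[["T50"]],
                 T75 = q[["T75"]], T95 = q[["T95"]],
                 stringsAsFactors = FALSE)
    }))
  }))

  dispersion <- lapply(c(F = "F", NF = "NF"), function(cs) {
    p <- profiles[profiles$caste == cs & !is.na(profiles$first_any_min), ,
                  drop = FALSE]
    t_end <- max(events$start_min) + 1
    if (nrow(p) >= 5 && sum(p$n_total) > 0) {
      dispersion_test(p$n_total, exposure = t_end - p$first_any_min)
    } else NULL
  })

  gravity <- gravity_summaries(events, castes)
  fg <- tryCatch(foreground_shares(events, castes, config$geometry),
                 error = function(e) NULL)
  troph_grid <- occupancy_grid(
    data.frame(minute = events$start_min, x_mm = events$x_mm,
               y_mm = events$y_mm),
    config$geometry)
  occ_corr <- if (!is.null(dat$positions)) {
    occ_grid <- occupancy_grid(dat$positions, config$geometry)
    grid_correlation(occ_grid, troph_grid)
  } else NULL
  uniformity <- spatial_uniformity_test(events, config$geometry,
                                        n_replicates = config$n_replicates,
                                        seed = config$seed + 4L)
  entrance <- entrance_distance_series(events, config$geometry, castes)

  report <- structure(list(
    profiles = profiles,
    caste_summary = caste_summary,
    network = list(metrics = metrics, efficiency = efficiency,
                   efficiency_vs_fr = eff_test,
                   pair_type_shares = shares,
                   pair_ratio = pratio, pair_ratio_vs_fr = pratio_test),
    inequality = list(summary = inequality_summary(profiles),
                      observed = gini_obs, scope = config$gini_scope,
                      vs_fr = gini_test),
    temporal = list(survival = surv, exponential_fit = expfit,
                    t50_vs_rp = t50_test, quantiles = quantiles,
                    dispersion = dispersion),
    spatial = list(gravity = gravity, foreground = fg,
                   troph_grid = troph_grid, occupancy_correlation = occ_corr,
                   uniformity = uniformity,
                   entrance_distance = entrance),
    provenance = list(seed = config$seed,
                      n_replicates = config$n_replicates,
                      n_events = nrow(events), n_ants = length(roster),
                      timestamp = format(t0),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")))
  ), class = "analysis_report")

  if (!is.null(config$out_dir)) export_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("trophallactic-network analysis report\n")
  cat(sprintf("  colony: %d ants, %d events\n", x$provenance$n_ants,
              x$provenance$n_events))
  cat(sprintf("  gini (%s ants) = %.3f vs FR null %.3f +/- %.3f (Z = %.2f, one-sided p = %.4g)\n",
              x$inequality$scope, x$inequality$observed,
              x$inequality$vs_fr$null_mean, x$inequality$vs_fr$null_sd,
              x$inequality$vs_fr$z, x$inequality$vs_fr$p))
  if (is.null(x$temporal$t50_vs_rp$error)) {
    cat(sprintf("  onset: tau = %.1f min (R2 = %.3f); T50 vs RP: Z = %.2f, p = %.4g\n",
                x$temporal$exponential_fit$tau_min,
                x$temporal$exponential_fit$r_squared,
                x$temporal$t50_vs_rp$z, x$temporal$t50_vs_rp$p))
  } else {
    cat(sprintf("  onset: tau = %.1f min (R2 = %.3f); T50 vs RP: %s\n",
                x$temporal$exponential_fit$tau_min,
                x$temporal$exponential_fit$r_squared,
                x$temporal$t50_vs_rp$error))
  }
  cat(sprintf("  efficiency = %.3f; pair ratio = %.3f\n",
              x$network$efficiency, x$network$pair_ratio))
  invisible(x)
}

#' Export the intermediate tables of a report as CSV
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(report$profiles, "profiles.csv")
  w(report$caste_summary, "caste_summary.csv")
  w(report$network$metrics, "node_metrics.csv")
  w(report$network$pair_type_shares, "pair_type_shares.csv")
  w(report$inequality$summary, "gini_summary.csv")
  w(report$temporal$survival, "naive_survival.csv")
  w(report$temporal$quantiles, "spread_quantiles.csv")
  w(report$spatial$gravity, "gravity_summaries.csv")
  w(report$spatial$troph_grid, "troph_grid.csv")
  w(report$spatial$entrance_distance, "entrance_distance.csv")
  invisible(dir)
}

#' Pool several colony reports
#'
#' Kruskal-Wallis homogeneity check of the per-ant total event counts
#' across colonies, plus pooled per-caste means and standard deviations.
#' With only two reports the pooled output carries a low-power warning
#' attribute.
#'
#' @param reports List of at least two `analysis_report`s.
#' @return List with `homogeneity` (Kruskal-Wallis on per-ant totals),
#'   `pooled` (per-caste pooled means +/- sd), `n_colonies`.
#' @export
multi_colony_summary <- function(reports) {
  if (length(reports) < 2) stop("need at least two colony reports")
  counts <- unlist(lapply(reports, function(r) r$profiles$n_total))
  colony <- rep(seq_along(reports),
                vapply(reports, function(r) nrow(r$profiles), integer(1)))
  kw <- stats::kruskal.test(counts, factor(colony))
  pooled <- do.call(rbind, lapply(c("F", "NF"), function(cs) {
    per <- lapply(reports, function(r) {
      p <- r$profiles[r$profiles$caste == cs, , drop = FALSE]
      c(mean_given = mean(p$n_given), mean_received = mean(p$n_received),
        mean_total = mean(p$n_total))
    })
    m <- do.call(rbind, per)
    data.frame(caste = cs,
               mean_given = mean(m[, 1]), sd_given = stats::sd(m[, 1]),
               mean_received = mean(m[, 2]), sd_received = stats::sd(m[, 2]),
               mean_total = mean(m[, 3]), sd_total = stats::sd(m[, 3]),
               stringsAsFactors = FALSE)
  }))
  out <- list(homogeneity = kw, pooled = pooled,
              n_colonies = length(reports))
  if (length(reports) == 2) attr(out, "low_power") <- TRUE
  out
}
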