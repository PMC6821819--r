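#' First qualifying event time per ant
#'
#' @param events Merged event data.frame.
#' @param roster Character vector of colony members.
#' @param role `"any"` (default), `"given"` or `"received"`.
#' @return Named numeric vector over the roster; NA for ants with no
#'   qualifying event.
#' @export
first_event_times <- function(events, roster, role = c("any", "given", "received")) {
  role <- match.arg(role)
  out <- stats::setNames(rep(NA_real_, length(roster)), roster)
  pick <- function(ids, times) {
    if (length(ids) == 0) return()
    agg <- tapply(times, ids, min)
    agg <- agg[names(agg) %in% roster]  # events may involve ants outside a sub-roster
    if (length(agg) == 0) return()
    out[names(agg)] <<- pmin(out[names(agg)], agg, na.rm = TRUE)
  }
  if (role %in% c("any", "given")) pick(events$donor, events$start_min)
  if (role %in% c("any", "received")) pick(events$receiver, events$start_min)
  out
}

#' Survival curve of naive ants
#'
#' Proportion of the reference population that has not yet performed its
#' first qualifying trophallactic event at each minute. The default
#' reference is the ants that performed at least one qualifying event
#' (`scope = "active"`); with `scope = "all"` ants that never act stay naive
#' throughout and the curve need not reach zero.
#'
#' @inheritParams first_event_times
#' @param scope `"active"` (default) or `"all"`.
#' @param t_max Last minute of the grid; defaults to the last event time.
#' @return data.frame with columns `minute` and `surviving` (proportion
#'   naive), starting at minute 0 with survival 1 when no event occurs at 0.
#' @export
naive_survival <- function(events, roster, role = c("any", "given", "received"),
                           scope = c("active", "all"), t_max = NULL) {
  role <- match.arg(role)
  scope <- match.arg(scope)
  ft <- first_event_times(events, roster, role)
  if (scope == "active") ft <- ft[!is.na(ft)]
  if (length(ft) == 0) stop("empty reference population")
  if (is.null(t_max)) t_max <- max(c(0, events$start_min))
  grid <- 0:t_max
  surviving <- vapply(grid, function(t) mean(is.na(ft) | ft > t), numeric(1))
  data.frame(minute = grid, surviving = surviving)
}

#' Exponential fit of a survival curve
#'
#' Least-squares regression of log survival on time over the points with
#' positive survival; the mean latency is tau = -1/slope. A non-decaying
#' curve (slope >= 0) yields a flagged result with `tau = NA`.
#'
#' @param curve Survival data.frame from [naive_survival()].
#' @return List with `tau_min`, `rate_per_min`, `r_squared`, `n_points`,
#'   `decaying` and the `lm` fit.
#' @export
fit_exponential <- function(curve) {
  keep <- curve$surviving > 0
  if (sum(keep) < 3) stop("need at least 3 points with positive survival")
  fit <- stats::lm(log(surviving) ~ minute, data = curve[keep, , drop = FALSE])
  slope <- unname(stats::coef(fit)[2])
  decaying <- is.finite(slope) && slope < 0
  list(tau_min = if (decaying) -1 / slope else NA_real_,
       rate_per_min = if (decaying) -slope else NA_real_,
       r_squared = summary(fit)$r.squared,
       n_points = sum(keep),
       decaying = decaying,
       fit = fit)
}

#' Spreading-time quantiles
#'
#' T_q is the earliest observed first-event time by which the cumulative
#' number of first events reaches `ceiling(q * reference_size)`. Quantiles
#' never reached within the observation window are NA.
#'
#' @param first_times Numeric vector of first-event times (NA = never).
#' @param reference_size Size of the reference population the proportions
#'   refer to; defaults to `length(first_times)`.
#' @param q Quantile levels.
#' @return Named numeric vector, e.g. `T50`, `T75`, `T95`.
#' @export
spread_quantiles <- function(first_times, reference_size = length(first_times),
                             q = c(0.5, 0.75, 0.95)) {
  stopifnot(reference_size >= 1)
  t <- sort(first_times[!is.na(first_times)])
  out <- vapply(q, function(qq) {
    k <- ceiling(qq * reference_size)
    if (k < 1) k <- 1
    if (length(t) >= k) t[k] else NA_real_
  }, numeric(1))
  stats::setNames(out, paste0("T", round(100 * q)))
}

#' Spreading speed versus the time-permutation null
#'
#' Compares the observed T50 of first-event times against its distribution
#' over time-permuted (RP) replicates. Spreading faster than the null gives
#' a negative Z. With `scope = "all"` (default) the T50 denominator is the
#' whole roster — the time by which half the colony has joined the exchange
#' network — so in a partially inactive colony the statistic probes the tail
#' of the joining process; `scope = "active"` uses the ants active in the
#' observed data (a median over joiners). Either reference is held fixed
#' across replicates (RP conserves the active set anyway). With a single
#' distinct event time the null is degenerate and the result is flagged.
#'
#' @param events Merged event data.frame (>= 2 events).
#' @param roster Character vector of colony members.
#' @param role Role defining the first event (see [first_event_times()]).
#' @param scope T50 denominator: `"all"` roster members or `"active"` ants.
#' @param n_replicates Ensemble size.
#' @param seed Integer master seed.
#' @param sidedness Passed to [z_test()]; defaults to `"less"` (is spreading
#'   faster than the null?).
#' @return `z_test_result` with the ensemble attached as `ensemble`. The
#'   call errors if the observed T50 is never reached within the window.
#' @export
spreading_vs_rp <- function(events, roster, role = "any",
                            scope = c("all", "active"),
                            n_replicates = 1000, seed = 1,
                            sidedness = "less") {
  scope <- match.arg(scope)
  stopifnot(nrow(events) >= 2)
  ref <- if (scope == "all") length(roster) else
    sum(!is.na(first_event_times(events, roster, role)))
  t50_stat <- function(e) {
    unname(spread_quantiles(first_event_times(e, roster, role),
                            reference_size = ref, q = 0.5))
  }
  obs <- t50_stat(events)
  if (is.na(obs)) {
    stop("observed T50 never reached within the observation window")
  }
  ens <- null_distribution(events, roster, model = "RP",
                           statistic = t50_stat,
                           n_replicates = n_replicates, seed = seed)
  res <- z_test(obs, ens, sidedness = sidedness)
  res$ensemble <- ens
  res
}

#' Rate regression of activity counts
#'
#' Ordinary least-squares fit of an event count on a covariate, over the
#' ants with a defined covariate value. Against the first-event time the
#' negated slope estimates the mean rate of trophallactic activity; against
#' the number of feeding visits the slope is events per visit. Spearman rank
#' statistics are reported alongside the linear fit.
#'
#' @param profiles Profile data.frame from [build_profiles()].
#' @param x Covariate column, e.g. `"first_given_min"`, `"first_any_min"`,
#'   `"n_visits"`.
#' @param y Count column, e.g. `"n_given"`, `"n_received"`, `"n_total"`.
#' @param caste Optional caste filter (`"F"` or `"NF"`).
#' @return Object of class `rate_fit`: list with `slope`, `slope_se`,
#'   `intercept`, `r_squared`, `p`, `spearman_rho`, `spearman_p`, `n`,
#'   `x`, `y`, `caste` and the `lm` fit.
#' @export
rate_regression <- function(profiles, x, y, caste = NULL) {
  d <- profiles
  if (!is.null(caste)) d <- d[d$caste == caste, , drop = FALSE]
  d <- d[!is.na(d[[x]]) & !is.na(d[[y]]), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 ants with defined covariate")
  if (stats::var(d[[x]]) == 0) stop("degenerate covariate: no variance in ", x)
  fit <- stats::lm(stats::reformulate(x, y), data = d)
  s <- summary(fit)
  sp <- suppressWarnings(
    stats::cor.test(d[[x]], d[[y]], method = "spearman"))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 slope_se = s$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p = s$coefficients[2, 4],
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 n = nrow(d), x = x, y = y, caste = caste,
                 fit = fit),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate fit %s ~ %s%s (n = %d): slope %.4g +/- %.4g, R2 = %.3f (Spearman rho %.3f, p %.3g)\n",
              x$y, x$x, if (is.null(x$caste)) "" else paste0(" [", x$caste, "]"),
              x$n, x$slope, x$slope_se, x$r_squared, x$spearman_rho,
              x$spearman_p))
  invisible(x)
}

#' Poisson overdispersion test of per-individual counts
#'
#' Fits an intercept-only log-link Poisson GLM to the counts, with an
#' optional log-exposure offset (e.g. remaining observation time after each
#' ant's first event, so that individuals starting at different times are
#' comparable). The dispersion statistic is the Pearson chi-square divided
#' by the residual degrees of freedom; under the Poisson null it is near 1,
#' and the upper chi-square tail of the Pearson statistic gives the p-value
#' of the overdispersion test.
#'
#' @param counts Non-negative integer counts, length >= 5, not all zero.
#' @param exposure Optional positive per-individual exposures.
#' @return Object of class `dispersion_result`: list with `dispersion`,
#'   `pearson_chisq`, `df`, `p`, `n`, `model`.
#' @export
dispersion_test <- function(counts, exposure = NULL) {
  stopifnot(length(counts) >= 5, all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero counts: dispersion undefined")
  if (is.null(exposure)) {
    fit <- stats::glm(counts ~ 1, family = stats::poisson())
    model <- "counts ~ 1 (constant exposure)"
  } else {
    stopifnot(length(exposure) == length(counts), all(exposure > 0))
    fit <- stats::glm(counts ~ 1 + offset(log(exposure)),
                      family = stats::poisson())
    model <- "counts ~ 1 + offset(log(exposure))"
  }
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  df <- fit$df.residual
  structure(list(dispersion = pearson / df,
                 pearson_chisq = pearson,
                 df = df,
                 p = stats::pchisq(pearson, df, lower.tail = FALSE),
                 n = length(counts),
                 model = model),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Poisson dispersion test (%s, n = %d): dispersion %.3f (chi2 %.2f on %d df), p = %.4g\n",
              x$model, x$n, x$dispersion, x$pearson_chisq, x$df, x$p))
  invisible(x)
}

#' Wald comparison of two regression slopes
#'
#' Two-sided Z-test on the difference between the slopes of two rate fits,
#' using the summed squared standard errors.
#'
#' @param fit_a,fit_b `rate_fit` objects with finite standard errors.
#' @return List with `z`, `p`, `slope_a`, `slope_b`.
#' @export
compare_rates <- function(fit_a, fit_b) {
  if (!is.finite(fit_a$slope_se) || !is.finite(fit_b$slope_se)) {
    stop("both fits need finite slope standard errors")
  }
  se <- sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
  z <- (fit_a$slope - fit_b$slope) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       slope_a = fit_a$slope, slope_b = fit_b$slope)
}
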