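#' Full Random (FR) edge rewiring
#'
#' Replaces every event's (donor, receiver) by an ordered pair of distinct
#' roster members drawn uniformly and independently per event, destroying all
#' structure of the observed network while conserving the event count and
#' the times, durations and positions of the events. Caste labels stay
#' attached to individuals, so caste-level contrasts remain meaningful.
#'
#' Draws from the current RNG state; seed management is done by the caller
#' (see [null_distribution()]).
#'
#' @param events Merged event data.frame (at least one event).
#' @param roster Character vector of colony members (length >= 2). Whether
#'   inactive ants are included is the caller's choice; the colony-level
#'   null uses the full roster.
#' @return Event data.frame with rewired donors and receivers.
#' @export
fr_rewire <- function(events, roster) {
  if (nrow(events) == 0) stop("fr_rewire requires at least one event")
  if (length(roster) < 2) stop("fr_rewire requires a roster of at least 2")
  m <- nrow(events)
  n <- length(roster)
  donors <- sample.int(n, m, replace = TRUE)
  # receiver uniform among the n - 1 others: shift draws past the donor
  shift <- sample.int(n - 1L, m, replace = TRUE)
  receivers <- (donors + shift - 1L) %% n + 1L
  events$donor <- roster[donors]
  events$receiver <- roster[receivers]
  events
}

#' Randomly Permuted times (RP)
#'
#' Permutes the multiset of start times uniformly among the events, leaving
#' the (donor, receiver) identities, durations and positions untouched. The
#' aggregate network, every per-ant count and every static statistic are
#' conserved exactly; only the temporal order is destroyed.
#'
#' @param events Merged event data.frame (at least two events).
#' @return Event data.frame with permuted `start_min`.
#' @export
rp_permute_times <- function(events) {
  if (nrow(events) < 2) stop("rp_permute_times requires at least two events")
  events$start_min <- events$start_min[sample.int(nrow(events))]
  events
}

#' Null distribution of a statistic under a reference model
#'
#' Applies the chosen reference model (`"FR"` rewiring or `"RP"` time
#' permutation) `n_replicates` times and evaluates `statistic` on each
#' randomized event list. Replicate r uses its own RNG stream seeded as
#' `seed + r` (a simple counter scheme), so ensembles are reproducible and
#' independent of evaluation order. Replicates on which the statistic fails
#' are recorded and excluded with a warning, never silently dropped.
#'
#' @param events Merged event data.frame.
#' @param roster Character vector of colony members (used by FR).
#' @param model `"FR"` or `"RP"`.
#' @param statistic Function mapping an event data.frame to a single number.
#' @param n_replicates Ensemble size (reference-model default 1000).
#' @param seed Integer master seed.
#' @return Object of class `null_ensemble`: list with `values`, `model`,
#'   `n_replicates`, `seed`, `n_failed`.
#' @export
null_distribution <- function(events, roster, model = c("FR", "RP"),
                              statistic, n_replicates = 1000, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1)
  randomize <- switch(model,
                      FR = function(e) fr_rewire(e, roster),
                      RP = rp_permute_times)
  values <- rep(NA_real_, n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    v <- tryCatch(statistic(randomize(events)), error = function(e) NA_real_)
    if (is.na(v)) n_failed <- n_failed + 1L else values[r] <- v
  }
  if (n_failed > 0) {
    warning(sprintf("statistic failed on %d of %d replicates", n_failed,
                    n_replicates))
  }
  structure(list(values = values[!is.na(values)], model = model,
                 n_replicates = n_replicates, seed = seed,
                 n_failed = n_failed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("%s null ensemble: %d replicates (seed %d), mean %.4g, sd %.4g\n",
              x$model, length(x$values), x$seed, mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Z-test of an observed statistic against a null ensemble
#'
#' Standardizes the observed value against the ensemble mean and standard
#' deviation and reports a normal-tail p-value, alongside an empirical
#' (rank-based) p for robustness. When the ensemble is degenerate (zero
#' standard deviation) the result is flagged and p is 0 or 1 by exact
#' comparison.
#'
#' @param observed Observed statistic.
#' @param ensemble `null_ensemble` or a numeric vector of null values.
#' @param sidedness `"two"`, `"greater"` (observed above null) or `"less"`.
#' @return Object of class `z_test_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `p_empirical`, `sidedness`,
#'   `degenerate`.
#' @export
z_test <- function(observed, ensemble, sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  values <- if (inherits(ensemble, "null_ensemble")) ensemble$values else ensemble
  if (length(values) == 0) stop("empty null ensemble")
  m <- mean(values)
  s <- stats::sd(values)
  if (length(values) == 1) s <- 0
  degenerate <- is.na(s) || s == 0
  if (degenerate) {
    z <- if (observed == m) 0 else sign(observed - m) * Inf
    p <- if (observed == m) 1 else 0
  } else {
    z <- (observed - m) / s
    p <- switch(sidedness,
                two = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
  }
  # empirical tail probability with the +1 rank correction
  n <- length(values)
  p_emp <- switch(sidedness,
                  greater = (sum(values >= observed) + 1) / (n + 1),
                  less = (sum(values <= observed) + 1) / (n + 1),
                  two = min(1, 2 * min((sum(values >= observed) + 1) / (n + 1),
                                       (sum(values <= observed) + 1) / (n + 1))))
  structure(list(observed = observed, null_mean = m, null_sd = s, z = z,
                 p = p, p_empirical = p_emp, sidedness = sidedness,
                 degenerate = degenerate),
            class = "z_test_result")
}

#' @export
print.z_test_result <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("Z-test unavailable:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("Z-test (%s-sided%s): observed %.4g vs null %.4g +/- %.4g; Z = %.3f, p = %.4g (empirical %.4g)\n",
              x$sidedness, if (x$degenerate) ", degenerate null" else "",
              x$observed, x$null_mean, x$null_sd, x$z, x$p, x$p_empirical))
  invisible(x)
}
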