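#' Lorenz curve of trophallactic activity
#'
#' Sorts per-ant activity counts in ascending order and accumulates the
#' population and activity shares, giving the piecewise-linear Lorenz curve
#' from (0, 0) to (1, 1). Ties are broken by position (ant order) for a
#' deterministic curve; the area under the curve, and hence the Gini
#' coefficient, is tie-invariant.
#'
#' @param activity Non-negative per-individual counts with positive total.
#' @return data.frame with columns `pop_share` and `activity_share`,
#'   including the (0, 0) origin.
#' @export
lorenz_curve <- function(activity) {
  stopifnot(length(activity) >= 1, all(activity >= 0))
  if (sum(activity) <= 0) stop("Lorenz curve undefined for all-zero activity")
  x <- sort(activity)
  n <- length(x)
  data.frame(pop_share = c(0, seq_len(n) / n),
             activity_share = c(0, cumsum(x) / sum(x)))
}

#' Gini coefficient of activity counts
#'
#' Computed as 1 minus twice the trapezoidal area under the ascending Lorenz
#' curve: 0 for perfect equality, (n-1)/n when a single individual accounts
#' for all activity. This is the standard coefficient matching the 0 =
#' equality / 1 = inequality convention.
#'
#' @inheritParams lorenz_curve
#' @return Numeric in \[0, 1\].
#' @export
gini_coefficient <- function(activity) {
  lc <- lorenz_curve(activity)
  area <- sum(diff(lc$pop_share) *
                (utils::head(lc$activity_share, -1) +
                 utils::tail(lc$activity_share, -1)) / 2)
  1 - 2 * area
}

#' Gini coefficients over scopes, activity kinds and castes
#'
#' Convenience table of Gini coefficients for each combination of scope
#' (all ants vs ants with at least one event), activity kind (total, given,
#' received events) and caste filter (colony, F, NF). Combinations whose
#' activity vector is empty or all-zero are reported as NA.
#'
#' @param profiles Profile data.frame from [build_profiles()].
#' @return data.frame with columns `scope`, `kind`, `caste`, `n`, `gini`.
#' @export
inequality_summary <- function(profiles) {
  grid <- expand.grid(scope = c("all", "active"),
                      kind = c("total", "given", "received"),
                      caste = c("colony", "F", "NF"),
                      stringsAsFactors = FALSE)
  col <- c(total = "n_total", given = "n_given", received = "n_received")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- profiles
    if (grid$caste[i] != "colony") p <- p[p$caste == grid$caste[i], , drop = FALSE]
    x <- p[[col[[grid$kind[i]]]]]
    if (grid$scope[i] == "active") x <- x[x > 0]
    g <- if (length(x) == 0 || sum(x) == 0) NA_real_ else gini_coefficient(x)
    data.frame(scope = grid$scope[i], kind = grid$kind[i],
               caste = grid$caste[i], n = length(x), gini = g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
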