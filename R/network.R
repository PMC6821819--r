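#' Build the directed weighted trophallactic network
#'
#' Aggregates merged events into a directed graph over the full roster:
#' weight(u -> v) = number of events in which u donated to v. Roster members
#' with no events are retained as isolated nodes so that colony-level
#' statistics use the true population.
#'
#' @param events Merged event data.frame.
#' @param castes Caste map from [assign_castes()].
#' @return An object of class `troph_network`: a list with the `igraph`
#'   graph (`graph`), the retained event list (`events`), the roster and the
#'   caste map.
#' @export
build_network <- function(events, castes) {
  roster <- castes$ant
  g <- igraph::make_empty_graph(n = length(roster), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = roster)
  if (nrow(events) > 0) {
    key <- paste(events$donor, events$receiver, sep = "\r")
    tab <- table(key)
    pairs <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]),
                           weight = as.numeric(tab))
  }
  g <- igraph::set_vertex_attr(g, "caste", value = castes$caste)
  act <- roster %in% c(events$donor, events$receiver)
  g <- igraph::set_vertex_attr(g, "active", value = act)
  structure(list(graph = g, events = events, roster = roster,
                 castes = castes),
            class = "troph_network")
}

#' @export
print.troph_network <- function(x, ...) {
  cat(sprintf("trophallactic network: %d ants (%d active), %d events, %d directed edges\n",
              length(x$roster), sum(igraph::V(x$graph)$active),
              nrow(x$events), igraph::ecount(x$graph)))
  invisible(x)
}

edge_lengths <- function(g) {
  # stronger exchange = shorter distance
  1 / igraph::E(g)$weight
}

#' Node-level centralities of the trophallactic network
#'
#' Computes, for every colony member, the weighted degree (total events given
#' plus received), betweenness and closeness on directed shortest paths with
#' edge length 1/weight, eigenvector centrality on the weighted adjacency,
#' and the weighted local clustering coefficient.
#'
#' Betweenness is normalised by (n-1)(n-2); closeness uses the harmonic
#' (per-reachable-pair) convention normalised by (n-1), so disconnected
#' graphs remain well defined (`closeness_mode = "component"` restricts the
#' classical closeness to each node's reachable set instead). Eigenvector
#' centrality is scaled to a maximum of 1; the default is computed on the
#' symmetrised (give + receive) adjacency so that one caste-comparable score
#' is reported, with the right/left (receive-/give-side) eigenvectors also
#' returned. On a graph with no edges all centralities are zero and the
#' result is flagged degenerate. Power-iteration convergence of each
#' eigenvector variant is recorded in the attributes `eigen_converged`,
#' `eigen_converged_give`, `eigen_converged_receive`; failure of the
#' default (symmetrised) variant raises a warning. Acyclic or
#' bipartite-like directional adjacencies are genuine degeneracies
#' (annihilation or period-2 oscillation) and are flagged, not silently
#' zeroed.
#'
#' @param net A `troph_network`.
#' @param closeness_mode `"harmonic"` (default) or `"component"`.
#' @return data.frame with one row per ant: `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, `eigenvector_give`, `eigenvector_receive`,
#'   `clustering`, plus a `degenerate` attribute flag.
#' @export
node_centralities <- function(net, closeness_mode = c("harmonic", "component")) {
  closeness_mode <- match.arg(closeness_mode)
  g <- net$graph
  n <- igraph::vcount(g)
  ants <- igraph::V(g)$name
  zero <- stats::setNames(numeric(n), ants)

  if (igraph::ecount(g) == 0 || n < 2) {
    res <- data.frame(ant = ants, degree = zero, betweenness = zero,
                      closeness = zero, eigenvector = zero,
                      eigenvector_give = zero, eigenvector_receive = zero,
                      clustering = zero, row.names = NULL,
                      stringsAsFactors = FALSE)
    attr(res, "degenerate") <- TRUE
    return(res)
  }

  w <- edge_lengths(g)
  degree <- igraph::strength(g, mode = "all")
  btw <- igraph::betweenness(g, directed = TRUE, weights = w,
                             normalized = TRUE)
  if (closeness_mode == "harmonic") {
    clo <- igraph::harmonic_centrality(g, mode = "out", weights = w,
                                       normalized = TRUE)
  } else {
    clo <- suppressWarnings(
      igraph::closeness(g, mode = "out", weights = w, normalized = TRUE))
    clo[!is.finite(clo)] <- 0
  }

  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE))
  eig_sym <- power_eigenvector((A + t(A)) / 2, shift = TRUE)
  eig_give <- power_eigenvector(A)       # scored through out-edges: donors
  eig_recv <- power_eigenvector(t(A))    # scored through in-edges: receivers

  # weighted local clustering (Barrat) on the underlying undirected graph,
  # reciprocal edges collapsed with summed weights
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "sum"))
  clu <- igraph::transitivity(gu, type = "barrat",
                              weights = igraph::E(gu)$weight,
                              isolates = "zero")

  res <- data.frame(ant = ants,
                    degree = as.numeric(degree),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(clo),
                    eigenvector = eig_sym$vector,
                    eigenvector_give = eig_give$vector,
                    eigenvector_receive = eig_recv$vector,
                    clustering = as.numeric(clu),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "degenerate") <- FALSE
  attr(res, "eigen_converged") <- eig_sym$converged
  attr(res, "eigen_converged_give") <- eig_give$converged
  attr(res, "eigen_converged_receive") <- eig_recv$converged
  if (!eig_sym$converged) {
    warning("eigenvector power iteration did not converge; values flagged")
  }
  res
}

# power iteration on a non-negative matrix; returns the dominant eigenvector
# scaled to max 1, with a convergence flag; a period-2 oscillation (paired
# +/- eigenvalues, e.g. bipartite-like digraphs) or annihilation (nilpotent
# adjacency) is a genuine degeneracy and exits unconverged
power_eigenvector <- function(A, tol = 1e-10, max_iter = 1e6, shift = FALSE) {
  n <- nrow(A)
  if (all(A == 0)) return(list(vector = numeric(n), converged = TRUE))
  # a positive diagonal shift keeps the eigenvectors of a non-negative
  # symmetric matrix but breaks the +/- eigenvalue pairing of bipartite
  # structures (stars, trees), guaranteeing convergence
  if (shift) A <- A + diag(max(A), n)
  v <- rep(1 / sqrt(n), n)
  v_prev <- v
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(A %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) break
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    if (i > 1 && max(abs(v_new - v_prev)) < tol) break  # oscillation
    v_prev <- v
    v <- v_new
  }
  v <- abs(v)
  if (max(v) > 0) v <- v / max(v)
  list(vector = v, converged = converged)
}

#' Global efficiency of the network
#'
#' Mean over all ordered node pairs (i != j) of the inverse shortest-path
#' distance 1/d(i, j), with 1/Inf = 0 for unreachable pairs. Distances are
#' directed with edge length 1/weight, so a complete unit-weight digraph has
#' efficiency 1 and an edgeless graph 0.
#'
#' @param net A `troph_network`.
#' @return Numeric in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  if (igraph::ecount(g) == 0) return(0)
  d <- igraph::distances(g, mode = "out", weights = edge_lengths(g))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Observed and expected caste pair-type shares
#'
#' Splits the events into the four directed caste pair types (F->F, F->NF,
#' NF->F, NF->NF) and reports each type's observed share together with the
#' share expected if every event were assigned to a uniformly random ordered
#' pair of distinct colony members (a caste-blind random pairing driven only
#' by the caste proportions).
#'
#' @param events Merged event data.frame (at least one event).
#' @param castes Caste map.
#' @return data.frame with columns `pair_type`, `n`, `observed`, `expected`.
#' @export
pair_type_shares <- function(events, castes) {
  if (nrow(events) == 0) stop("pair_type_shares requires at least one event")
  dc <- caste_of(castes, events$donor)
  rc <- caste_of(castes, events$receiver)
  type <- paste0(dc, "->", rc)
  lev <- c("F->F", "F->NF", "NF->F", "NF->NF")
  obs <- table(factor(type, levels = lev))

  n <- nrow(castes)
  nf <- sum(castes$caste == "F")
  nn <- n - nf
  tot <- n * (n - 1)
  expected <- c(nf * (nf - 1), nf * nn, nn * nf, nn * (nn - 1)) / tot

  data.frame(pair_type = lev,
             n = as.integer(obs),
             observed = as.numeric(obs) / nrow(events),
             expected = expected,
             stringsAsFactors = FALSE)
}

#' Ratio of distinct directed pairs to total events
#'
#' A ratio of 1 means every event happened between a fresh (donor, receiver)
#' pair; small values indicate repeated use of the same partnerships.
#'
#' @param events Merged event data.frame (at least one event).
#' @return Numeric in (0, 1\].
#' @export
pair_ratio <- function(events) {
  if (nrow(events) == 0) stop("pair_ratio requires at least one event")
  length(unique(paste(events$donor, events$receiver, sep = "\r"))) /
    nrow(events)
}

#' Linear relation between partner count and event count
#'
#' Ordinary least-squares fit of the number of distinct trophallactic
#' partners on the number of events, over active ants.
#'
#' @param profiles Profile data.frame from [build_profiles()].
#' @return List with `slope`, `intercept`, `r_squared`, `n` and the `lm` fit.
#' @export
partner_event_correlation <- function(profiles) {
  act <- profiles[profiles$active, , drop = FALSE]
  if (nrow(act) < 3) stop("need at least 3 active ants")
  fit <- stats::lm(n_partners ~ n_total, data = act)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       n = nrow(act),
       fit = fit)
}
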