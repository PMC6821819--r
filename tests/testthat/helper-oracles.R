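# brute-force graph oracles for small (<= 6 node) directed weighted graphs,
# independent of the igraph-backed implementation

# enumerate every simple path from i to j; return list of path lengths
# (sum of edge lengths) and the paths themselves
bf_all_paths <- function(len_mat, i, j) {
  n <- nrow(len_mat)
  out <- list()
  walk <- function(path, total) {
    v <- path[length(path)]
    if (v == j) {
      out[[length(out) + 1]] <<- list(path = path, length = total)
      return()
    }
    for (w in seq_len(n)) {
      if (is.finite(len_mat[v, w]) && !(w %in% path)) {
        walk(c(path, w), total + len_mat[v, w])
      }
    }
  }
  walk(i, 0)
  out
}

# all-pairs shortest distances, number of shortest paths, and betweenness
# by exhaustive simple-path enumeration
bf_graph_metrics <- function(len_mat, tol = 1e-12) {
  n <- nrow(len_mat)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  btw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      paths <- bf_all_paths(len_mat, i, j)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "length")
      d[i, j] <- min(lens)
      shortest <- paths[lens <= min(lens) + tol]
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p$path, c(i, j))
        btw[inner] <- btw[inner] + 1 / sigma
      }
    }
  }
  # normalizations matching the implementation's conventions
  harm <- vapply(seq_len(n), function(i) {
    sum(1 / d[i, -i][is.finite(d[i, -i])]) / (n - 1)
  }, numeric(1))
  eff <- {
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n * (n - 1))
  }
  list(dist = d,
       betweenness = if (n > 2) btw / ((n - 1) * (n - 2)) else btw,
       harmonic_out = harm,
       efficiency = eff)
}

# edge length matrix (1/weight) from an event list over given node order
bf_length_matrix <- function(events, nodes) {
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(events))) {
    w[events$donor[k], events$receiver[k]] <-
      w[events$donor[k], events$receiver[k]] + 1
  }
  len <- 1 / w
  len
}
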