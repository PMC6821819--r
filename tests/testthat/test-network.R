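test_that("the aggregate network conserves events as edge weights", {
  castes <- make_castes(c("A", "B", "C", "D"))
  net <- build_network(make_events(c("A", "A", "B"), c("B", "B", "C")), castes)
  g <- net$graph
  expect_equal(igraph::vcount(g), 4)            # isolated D retained
  expect_equal(sum(igraph::E(g)$weight), 3)
  ab <- igraph::get_edge_ids(g, c("A", "B"))
  expect_equal(igraph::E(g)$weight[ab], 2)

  empty <- build_network(make_events(character(0), character(0)), castes)
  expect_equal(igraph::ecount(empty$graph), 0)
  expect_equal(igraph::vcount(empty$graph), 4)
})

test_that("centralities agree with exhaustive path enumeration on small graphs", {
  cases <- list(
    star = make_events(rep("A", 3), c("B", "C", "D")),
    path = make_events(c("A", "B"), c("B", "C")),
    dyads = make_events(c("A", "C"), c("B", "D")),
    weighted = make_events(c("A", "A", "B", "C", "C", "D", "A"),
                           c("B", "B", "C", "D", "A", "B", "E")),
    cycle5 = make_events(c("A", "B", "C", "D", "E"),
                         c("B", "C", "D", "E", "A"))
  )
  for (nm in names(cases)) {
    ev <- cases[[nm]]
    nodes <- sort(unique(c(ev$donor, ev$receiver)))
    castes <- make_castes(nodes)
    net <- build_network(ev, castes)
    m <- node_centralities(net)
    m <- m[match(nodes, m$ant), ]
    oracle <- bf_graph_metrics(bf_length_matrix(ev, nodes))
    expect_equal(m$betweenness, oracle$betweenness, tolerance = 1e-10,
                 info = nm)
    expect_equal(m$closeness, oracle$harmonic_out, tolerance = 1e-10,
                 info = nm)
    expect_equal(global_efficiency(net), oracle$efficiency,
                 tolerance = 1e-10, info = nm)
    expect_true(all(m$eigenvector >= 0 & m$eigenvector <= 1))
    expect_true(all(m$clustering >= 0 & m$clustering <= 1))
  }
})

test_that("a directed star has no through-paths and reachable leaves", {
  net <- build_network(make_events(rep("A", 3), c("B", "C", "D")),
                       make_castes(c("A", "B", "C", "D")))
  m <- node_centralities(net)
  expect_equal(m$betweenness[m$ant == "A"], 0)
  expect_gt(m$closeness[m$ant == "A"], 0)   # center reaches all leaves
  expect_equal(m$closeness[m$ant == "B"], 0) # leaves reach nobody (out-mode)
  expect_equal(m$degree[m$ant == "A"], 3)
  # the acyclic directional adjacency is a flagged degeneracy, the
  # symmetrised default still converges
  expect_true(attr(m, "eigen_converged"))
  expect_false(attr(m, "eigen_converged_give"))
})

test_that("degenerate graphs give flagged all-zero centralities", {
  net <- build_network(make_events(character(0), character(0)),
                       make_castes(c("A", "B")))
  m <- node_centralities(net)
  expect_true(attr(m, "degenerate"))
  expect_true(all(m[, -1] == 0))
})

test_that("global efficiency matches hand values and is monotone", {
  castes <- make_castes(c("A", "B", "C"))
  path <- build_network(make_events(c("A", "B"), c("B", "C")), castes)
  expect_equal(global_efficiency(path), (1 + 1 / 2 + 1) / 6,
               tolerance = 1e-12)
  expect_equal(global_efficiency(
    build_network(make_events(character(0), character(0)), castes)), 0)

  # adding unit-weight edges never decreases efficiency
  set.seed(1)
  nodes <- c("A", "B", "C", "D", "E")
  pairs <- expand.grid(d = nodes, r = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$d != pairs$r, ]
  ord <- sample(nrow(pairs))
  eff_prev <- 0
  for (k in seq(2, 20, by = 2)) {
    ev <- make_events(pairs$d[ord[1:k]], pairs$r[ord[1:k]])
    eff <- global_efficiency(build_network(ev, make_castes(nodes)))
    expect_gte(eff, eff_prev - 1e-12)
    eff_prev <- eff
  }
})

test_that("pair-type shares match enumeration of ordered caste pairs", {
  # one forager, one non-forager: only cross pairs exist
  castes2 <- make_castes(c("A", "B"), foragers = "A")
  s2 <- pair_type_shares(make_events("A", "B"), castes2)
  expect_equal(s2$expected, c(0, 0.5, 0.5, 0))
  expect_equal(s2$observed, c(0, 1, 0, 0))

  # 2 F, 8 NF: F->F expected share = 2/90
  roster10 <- sprintf("w%02d", 1:10)
  castes10 <- make_castes(roster10, foragers = roster10[1:2])
  s10 <- pair_type_shares(make_events("w01", "w03"), castes10)
  expect_equal(s10$expected[s10$pair_type == "F->F"], 2 / 90)
  expect_equal(sum(s10$expected), 1, tolerance = 1e-12)
  expect_equal(sum(s10$observed), 1, tolerance = 1e-12)
  expect_error(pair_type_shares(make_events(character(0), character(0)),
                                castes10), "at least one event")
})

test_that("expected pair-type shares match caste-blind random assignment", {
  roster <- sprintf("w%02d", 1:8)
  castes <- make_castes(roster, foragers = roster[1:2])
  ev <- make_events(rep("w01", 5), rep("w03", 5))
  n_rep <- 10000
  counts <- c(`F->F` = 0, `F->NF` = 0, `NF->F` = 0, `NF->NF` = 0)
  set.seed(123)
  for (r in seq_len(n_rep)) {
    rew <- fr_rewire(ev, roster)
    dc <- castes$caste[match(rew$donor, castes$ant)]
    rc <- castes$caste[match(rew$receiver, castes$ant)]
    tab <- table(factor(paste0(dc, "->", rc), levels = names(counts)))
    counts <- counts + as.numeric(tab)
  }
  emp <- counts / (n_rep * nrow(ev))
  expected <- pair_type_shares(ev, castes)$expected
  se <- sqrt(expected * (1 - expected) / (n_rep * nrow(ev)))
  expect_true(all(abs(emp - expected) < 3 * se))
})

test_that("pair ratio counts distinct directed pairs per event", {
  expect_equal(pair_ratio(make_events(c("A", "B"), c("B", "C"))), 1)
  expect_equal(pair_ratio(make_events(c("A", "A", "A", "B"),
                                      c("B", "B", "B", "C"))), 0.5)
  expect_equal(pair_ratio(make_events("A", "B")), 1)
})

test_that("partner-event correlation recovers exact linear structure", {
  p <- data.frame(ant = letters[1:5], caste = "NF",
                  n_total = c(1, 2, 3, 4, 5),
                  n_partners = c(1, 2, 3, 4, 5),
                  active = TRUE)
  fit <- suppressWarnings(partner_event_correlation(p))  # exact fit warns in lm
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  p$n_partners <- 2
  expect_equal(suppressWarnings(partner_event_correlation(p))$slope, 0,
               tolerance = 1e-12)

  expect_error(partner_event_correlation(p[1:2, ]), "at least 3")
})
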