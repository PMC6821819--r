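test_that("nest geometry validates the entrance and derives the grid", {
  g <- nest_geometry()
  expect_equal(g$cell_w_mm, 56 / 6, tolerance = 1e-12)
  expect_equal(g$cell_h_mm, 41 / 5, tolerance = 1e-12)
  expect_equal(g$split_axis, "x")
  expect_error(nest_geometry(entrance_mm = c(10, 10)), "boundary")
  gb <- nest_geometry(entrance_mm = c(28, 0))
  expect_equal(gb$split_axis, "y")
})

test_that("gravity centres and dispersions follow hand geometry", {
  castes <- make_castes(c("A", "B"))
  ev <- make_events(c("A", "A"), c("B", "B"), x_mm = c(0, 20),
                    y_mm = c(0, 20))
  gs <- gravity_summaries(ev, castes)
  a <- gs[gs$ant == "A", ]
  expect_equal(c(a$gx_mm, a$gy_mm), c(10, 10))
  expect_equal(a$mean_dist_cm, sqrt(200) / 10, tolerance = 1e-12)

  single <- gravity_summaries(make_events("A", "B", x_mm = 5, y_mm = 9),
                              castes)
  expect_equal(single$mean_dist_cm, c(0, 0))

  corners <- make_events(rep("A", 4), rep("B", 4),
                         x_mm = c(10, 10, 30, 30), y_mm = c(10, 30, 10, 30))
  gc <- gravity_summaries(corners, castes)[1, ]
  expect_equal(c(gc$gx_mm, gc$gy_mm), c(20, 20))
  expect_equal(gc$mean_dist_cm, sqrt(200) / 10, tolerance = 1e-12)
})

test_that("gravity dispersion is translation invariant and role-flagged", {
  castes <- make_castes(c("A", "B", "C"))
  set.seed(8)
  ev <- make_events(sample(c("A", "B"), 20, replace = TRUE), "C",
                    x_mm = runif(20, 0, 30), y_mm = runif(20, 0, 30))
  ev$donor[1] <- "A"
  g1 <- gravity_summaries(ev, castes)
  ev2 <- ev
  ev2$x_mm <- ev2$x_mm + 11
  ev2$y_mm <- ev2$y_mm + 7
  g2 <- gravity_summaries(ev2, castes)
  expect_equal(g1$mean_dist_cm, g2$mean_dist_cm, tolerance = 1e-12)
  expect_true(all(g1$received_any[g1$ant == "C"]))
  expect_false(any(g1$gave_any[g1$ant == "C"]))
})

test_that("grid binning is exhaustive, half-open and conservative", {
  geom <- nest_geometry()
  pts <- data.frame(minute = c(0, 0, 95),
                    x_mm = c(0, 56, 10), y_mm = c(0, 41, 10))
  grid <- occupancy_grid(pts, geom)
  expect_equal(sum(grid$count), 3)
  expect_equal(grid$count[grid$window == 0 & grid$col == 0 & grid$row == 0], 1)
  expect_equal(grid$count[grid$window == 0 & grid$col == 5 & grid$row == 4], 1)
  expect_equal(grid$count[grid$window == 9 & grid$col == 1 & grid$row == 1], 1)

  expect_error(occupancy_grid(data.frame(minute = 0, x_mm = -1, y_mm = 2),
                              geom), "outside nest bounds")

  set.seed(12)
  many <- data.frame(minute = sample(0:89, 500, replace = TRUE),
                     x_mm = runif(500, 0, 56), y_mm = runif(500, 0, 41))
  expect_equal(sum(occupancy_grid(many, geom)$count), 500)
})

test_that("grid correlations detect identity, reversal and independence", {
  geom <- nest_geometry(grid_ncol = 4, grid_nrow = 3)
  set.seed(3)
  pts <- data.frame(minute = 0, x_mm = runif(200, 0, 56),
                    y_mm = runif(200, 0, 41))
  g <- occupancy_grid(pts, geom)
  expect_equal(grid_correlation(g, g)$rho, 1)

  rev <- g
  rev$count <- max(g$count) - g$count
  expect_equal(grid_correlation(g, rev)$rho, -1)

  flat <- g
  flat$count <- 2L
  expect_true(grid_correlation(g, flat)$degenerate)

  rhos <- replicate(200, {
    a <- g
    b <- g
    a$count <- rpois(nrow(g), 3)
    b$count <- rpois(nrow(g), 3)
    r <- grid_correlation(a, b)
    if (r$degenerate) NA else r$rho
  })
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.05)
})

test_that("foreground shares split donations at the entrance half", {
  geom <- nest_geometry()  # entrance left wall, foreground x < 28
  castes <- make_castes(c("F1", "N1"), foragers = "F1")
  ev <- rbind(
    make_events(rep("F1", 4), rep("N1", 4), x_mm = c(5, 10, 40, 50),
                y_mm = 20),
    make_events(rep("N1", 4), rep("F1", 4), x_mm = c(5, 40, 45, 50),
                y_mm = 20)
  )
  fs <- foreground_shares(ev, castes, geom)
  expect_equal(fs$table$share[fs$table$caste == "F"], 0.5)
  expect_equal(fs$table$share[fs$table$caste == "NF"], 0.25)
  m <- matrix(c(2, 2, 1, 3), 2, byrow = TRUE)
  expect_equal(fs$p, suppressWarnings(stats::chisq.test(m))$p.value)

  all_fg <- make_events(c("F1", "N1"), c("N1", "F1"), x_mm = 1, y_mm = 20)
  expect_true(foreground_shares(all_fg, castes, geom)$degenerate)
  only_f <- make_events("F1", "N1", x_mm = 1, y_mm = 20)
  expect_error(foreground_shares(only_f, castes, geom), "per caste")
})

test_that("entrance distances use hand geometry and track drift", {
  geom <- nest_geometry()  # entrance (0, 20.5)
  at_entrance <- make_events("A", "B", x_mm = 0, y_mm = 20.5)
  s0 <- entrance_distance_series(at_entrance, geom)
  expect_equal(s0$mean_dist_cm, 0)

  far <- make_events("A", "B", x_mm = 56, y_mm = 41)
  expect_equal(entrance_distance_series(far, geom)$mean_dist_cm,
               sqrt(56^2 + 20.5^2) / 10, tolerance = 1e-12)

  drift <- make_events(rep("A", 9), rep("B", 9),
                       start_min = c(1, 5, 11, 15, 21, 25, 31, 35, 41),
                       x_mm = seq(5, 45, by = 5), y_mm = 20.5)
  sd_ <- entrance_distance_series(drift, geom)
  expect_true(all(diff(sd_$mean_dist_cm) > 0))
})

test_that("clustered events fail the spatial uniformity null", {
  geom <- nest_geometry()
  set.seed(11)
  clustered <- make_events(rep("A", 40), rep("B", 40),
                           x_mm = runif(40, 2, 6), y_mm = runif(40, 2, 6))
  res <- spatial_uniformity_test(clustered, geom, n_replicates = 200,
                                 seed = 2)
  expect_gt(res$z, 3)
  expect_lt(res$p, 0.01)

  set.seed(4)
  uniform <- make_events(rep("A", 60), rep("B", 60),
                         x_mm = runif(60, 0, 56), y_mm = runif(60, 0, 41))
  res_u <- spatial_uniformity_test(uniform, geom, n_replicates = 200,
                                   seed = 2)
  expect_lt(abs(res_u$z), 3)
})
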