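test_that("scan tables are read, validated and sorted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("minute,donor,receiver,x_mm,y_mm",
               "5,B,C,10,10", "1,A,B,3,4", "5,A,C,1,2"), path)
  roster <- c("A", "B", "C")
  scans <- read_scan_table(path, roster)
  expect_equal(nrow(scans), 3)
  expect_equal(scans$minute, c(1L, 5L, 5L))
  expect_equal(scans$donor, c("A", "A", "B"))

  writeLines("minute,donor,receiver,x_mm,y_mm", path)
  expect_equal(nrow(read_scan_table(path, roster)), 0)

  writeLines(c("minute,donor,x_mm,y_mm", "1,A,3,4"), path)
  expect_error(read_scan_table(path, roster), "missing column")
})

test_that("scan validation rejects self-contacts, unknown ants, out-of-nest points", {
  roster <- c("A", "B")
  expect_error(validate_scan_records(make_scans(1, "A", "A"), roster),
               "donor equals receiver.*1")
  expect_error(validate_scan_records(make_scans(1, "A", "Z"), roster),
               "not in the roster")
  geom <- nest_geometry()
  bad <- make_scans(1, "A", "B", x_mm = 60, y_mm = 5)
  expect_error(validate_scan_records(bad, roster, geom), "outside nest bounds")
  expect_silent(validate_scan_records(make_scans(1, "A", "B", 56, 41),
                                      roster, geom))
})

test_that("consecutive same-pair scans merge into single events", {
  scans <- make_scans(c(10, 11, 13), rep("A", 3), rep("B", 3))
  ev <- merge_consecutive_scans(scans)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_min, c(10L, 13L))
  expect_equal(ev$duration_min, c(2L, 1L))

  single <- merge_consecutive_scans(make_scans(5, "A", "B"))
  expect_equal(single$duration_min, 1L)

  # role swap on consecutive minutes breaks the run
  swap <- merge_consecutive_scans(make_scans(c(4, 5), c("A", "B"), c("B", "A")))
  expect_equal(nrow(swap), 2)
  expect_equal(swap$duration_min, c(1L, 1L))
})

test_that("event position comes from the first scan of a run", {
  scans <- data.frame(minute = c(3L, 4L), donor = "A", receiver = "B",
                      x_mm = c(7, 9), y_mm = c(2, 5))
  ev <- merge_consecutive_scans(scans)
  expect_equal(ev$x_mm, 7)
  expect_equal(ev$y_mm, 2)
})

test_that("merging is idempotent through scan expansion and conserves counts", {
  set.seed(42)
  for (i in 1:10) {
    n <- 30
    scans <- make_scans(sample(0:20, n, replace = TRUE),
                        sample(c("A", "B", "C"), n, replace = TRUE),
                        "Z")
    scans <- scans[scans$donor != scans$receiver, , drop = FALSE]
    scans <- scans[!duplicated(scans[c("minute", "donor", "receiver")]), ,
                   drop = FALSE]
    ev <- merge_consecutive_scans(scans)
    expect_lte(nrow(ev), nrow(scans))
    expect_equal(sum(ev$duration_min), nrow(scans))
    ev2 <- merge_consecutive_scans(events_to_scans(ev))
    expect_equal(ev2[order(ev2$start_min, ev2$donor, ev2$receiver), ],
                 ev[order(ev$start_min, ev$donor, ev$receiver), ])
  }
})

test_that("caste assignment requires one visit at or above the threshold", {
  roster <- c("A", "B", "C")
  visits <- data.frame(ant = c("A", "B", "B", "B"),
                       start_s = c(10, 5, 40, 90),
                       duration_s = c(6, 2, 3, 3))
  cm <- assign_castes(visits, roster)
  expect_equal(cm$caste[cm$ant == "A"], "F")   # one 6-s visit
  expect_equal(cm$caste[cm$ant == "B"], "NF")  # 2+3+3 s, none >= 5
  expect_equal(cm$caste[cm$ant == "C"], "NF")  # never visited
  expect_error(assign_castes(data.frame(ant = "Z", start_s = 1, duration_s = 9),
                             roster), "not in the roster")
})

test_that("raising the caste threshold never converts NF to F", {
  set.seed(7)
  roster <- sprintf("w%02d", 1:20)
  visits <- data.frame(ant = sample(roster, 40, replace = TRUE),
                       start_s = runif(40, 0, 5000),
                       duration_s = rexp(40, 1 / 6))
  prev <- NULL
  for (thr in c(2, 5, 10, 20)) {
    cm <- assign_castes(visits, roster, threshold_s = thr)
    if (!is.null(prev)) {
      expect_false(any(prev$caste == "NF" & cm$caste == "F"))
    }
    prev <- cm
  }
})

test_that("profiles tally counts, balances, partners and first times", {
  castes <- make_castes(c("A", "B", "C", "D"), foragers = "A")
  ev <- make_events(c("A", "A"), c("B", "C"), start_min = c(3, 7))
  p <- build_profiles(ev, no_visits(), castes)
  pa <- p[p$ant == "A", ]
  expect_equal(pa$n_given, 2)
  expect_equal(pa$n_received, 0)
  expect_equal(pa$balance, 2)
  expect_equal(pa$n_partners, 2)
  expect_equal(pa$first_given_min, 3)
  expect_true(is.na(pa$first_received_min))
  expect_equal(p$balance[p$ant == "B"], -1)

  pd <- p[p$ant == "D", ]
  expect_equal(pd$n_total, 0)
  expect_true(is.na(pd$first_any_min))
  expect_false(pd$active)

  sym <- build_profiles(make_events(c("A", "B"), c("B", "A")), no_visits(),
                        castes)
  expect_equal(sym$balance[sym$ant %in% c("A", "B")], c(0, 0))
})

test_that("activity is conserved across the colony", {
  set.seed(99)
  roster <- sprintf("w%02d", 1:12)
  castes <- make_castes(roster, foragers = roster[1:3])
  for (i in 1:10) {
    n <- 40
    d <- sample(roster, n, replace = TRUE)
    r <- sample(roster, n, replace = TRUE)
    keep <- d != r
    ev <- make_events(d[keep], r[keep],
                      start_min = sample(0:89, sum(keep), replace = TRUE))
    p <- build_profiles(ev, no_visits(), castes)
    expect_equal(sum(p$n_given), nrow(ev))
    expect_equal(sum(p$n_received), nrow(ev))
    expect_equal(sum(p$balance), 0)
    expect_true(all(p$n_partners <= p$n_total))
  }
})
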