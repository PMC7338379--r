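test_that("simulate_events validates inputs and honours degenerate mixtures", {
  expect_error(simulate_events(1.2, 100), "live_fraction")
  expect_error(simulate_events(0.5, 0), "n_events")
  expect_error(simulate_events(0.5, 100, live_mu = 100, dead_mu = 50),
               "dead_mu")
  # pure-live pool: every event from the low component; with well-separated
  # medians no event crosses the midpoint gate
  tab <- simulate_events(1.0, 5000, live_mu = 100, dead_mu = 1e4,
                         sigma = 0.5, seed = 3)
  expect_equal(gate_viability(tab, default_gate())$live_fraction, 1.0)
  tab0 <- simulate_events(0.0, 5000, seed = 3)
  expect_equal(gate_viability(tab0, default_gate())$live_fraction, 0.0)
})

test_that("gating counts events below the threshold", {
  t <- 1000
  tab <- structure(list(events = c(0.5 * t, 2 * t, 0.9 * t, 3 * t),
                        pool_id = "p", n_events = 4L),
                   class = "flow_event_table")
  expect_equal(gate_viability(tab, t)$live_fraction, 0.5)
  expect_error(gate_viability(tab, 0), "positive")
  empty <- structure(list(events = numeric(0), pool_id = "p", n_events = 0L),
                     class = "flow_event_table")
  expect_error(gate_viability(empty), "empty")
})

test_that("gated live fraction recovers the true mixture weight", {
  tab <- simulate_events(0.8, 50000, seed = 17)
  lf <- gate_viability(tab, default_gate())$live_fraction
  expect_lt(abs(lf - 0.8), 3 * sqrt(0.8 * 0.2 / 50000) + 0.005)
})

test_that("viability labels follow the three published bands", {
  expect_identical(label_from_viability(c(0.85, 0.50, 0.30)),
                   c("unaffected", "mildly_affected", "affected"))
  expect_identical(label_from_viability(c(0, 1)), c("affected", "unaffected"))
  # the uncovered band (0.60, 0.80] and the 0.80 boundary are unlabeled;
  # 0.40 belongs to the closed mildly-affected interval
  expect_identical(label_from_viability(c(0.70, 0.80)),
                   c("unlabeled", "unlabeled"))
  expect_identical(label_from_viability(c(0.40, 0.60)),
                   c("mildly_affected", "mildly_affected"))
  expect_error(label_from_viability(1.1), "live_fraction")
  expect_error(label_from_viability(-0.1), "live_fraction")
})

test_that("the label function is total and piecewise constant on [0, 1]", {
  grid <- seq(0, 1, by = 0.001)
  labs <- label_from_viability(grid)
  expect_true(all(labs %in% c("unaffected", "mildly_affected", "affected",
                              "unlabeled")))
  # exactly four plateaus: affected | mildly | unlabeled | unaffected
  expect_identical(rle(labs)$values,
                   c("affected", "mildly_affected", "unlabeled", "unaffected"))
})

test_that("event tables round-trip through CSV", {
  tabs <- list(simulate_events(0.9, 50, seed = 1, pool_id = "a"),
               simulate_events(0.2, 30, seed = 2, pool_id = "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(tabs, path)
  back <- read_flow_csv(path)
  expect_setequal(names(back), c("a", "b"))
  expect_equal(back$a$events, tabs[[1]]$events)
  expect_equal(back$b$n_events, 30L)
})
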