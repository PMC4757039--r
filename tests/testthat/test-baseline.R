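gear <- gear_config()

test_that("movement thresholds are fraction x extension + baseline s.d.", {
  seg <- data.frame(baseline_sd_m = c(0, 0.04, 0.12))
  expect_equal(movement_threshold(seg, 1, gear), c(0.60, 0.64, 0.72))
  expect_equal(movement_threshold(seg, 0.5, gear), c(0.30, 0.34, 0.42))
  expect_error(movement_threshold(seg, 0.75, gear), "threshold_fractions")
  expect_error(movement_threshold(data.frame(baseline_sd_m = -1), 1, gear),
               ">= 0")
})

test_that("a capture shorter than the recalc interval yields a single segment", {
  tr <- make_flat_trace(1000) # 2000 s
  sched <- build_baseline_schedule(tr, 120, 120 + 20 * 60, gear)
  expect_equal(nrow(sched), 1L)
  expect_equal(sched$start_s, 120)
  expect_equal(sched$end_s, 120 + 1200)
  expect_equal(sched$baseline_depth_m, 8)
  expect_equal(sched$baseline_sd_m, 0)
})

test_that("segments break at 30-min marks and track linear tidal drift", {
  # 0.5 m/h drift, zero noise; 90-min capture starting at t = 120 s
  dt <- 2
  n <- 3000
  drift <- 0.5 / 3600 * seq(0, by = dt, length.out = n)
  tr <- make_flat_trace(n, depth = 8, add = drift)
  sched <- build_baseline_schedule(tr, 120, 120 + 90 * 60, gear, refine = FALSE)
  expect_equal(nrow(sched), 3L)
  expect_equal(sched$start_s, 120 + c(0, 1800, 3600))
  expect_equal(sched$end_s, 120 + c(1800, 3600, 5400))
  # successive baselines differ by drift x 30 min = 0.25 m
  expect_equal(diff(sched$baseline_depth_m), rep(0.25, 2), tolerance = 1e-6)
})

test_that("schedule preconditions are enforced", {
  tr <- make_flat_trace(200)
  expect_error(build_baseline_schedule(tr, 30, 300, gear), "baseline window")
  expect_error(build_baseline_schedule(tr, 200, 100, gear), "exceed")
})

test_that("deviation series is |depth - covering baseline| on [capture, haul)", {
  tr <- make_flat_trace(500)
  sched <- build_baseline_schedule(tr, 100, 900, gear)
  dev <- deviation_series(tr, sched)
  expect_true(all(dev$deviation_m == 0))
  expect_equal(range(dev$time_s), c(100, 898)) # haul sample excluded
  # forced arithmetic: baseline 8.0, sample at 7.4 -> 0.6
  tr2 <- make_flat_trace(500)
  tr2$depths[100] <- 7.4
  dev2 <- deviation_series(tr2, sched)
  expect_equal(dev2$deviation_m[dev2$time_s == tr2$times[100]], 0.6)
})

test_that("deviations match an independent per-sample recomputation", {
  set.seed(42)
  n <- 2000
  tr <- make_flat_trace(n, depth = 10, add = rnorm(n, 0, 0.05))
  sched <- build_baseline_schedule(tr, 200, 3800, gear, refine = FALSE)
  dev <- deviation_series(tr, sched)
  # brute-force loop oracle
  expected <- vapply(seq_len(nrow(dev)), function(i) {
    t <- dev$time_s[i]
    seg <- which(sched$start_s <= t & t < sched$end_s)
    expect_length(seg, 1L)
    abs(tr$depths[tr$times == t] - sched$baseline_depth_m[seg])
  }, numeric(1))
  expect_equal(dev$deviation_m, expected)
})

test_that("a sample exactly on a 30-min boundary belongs to the later segment", {
  tr <- make_flat_trace(2000)
  sched <- build_baseline_schedule(tr, 100, 100 + 3600, gear, refine = FALSE)
  dev <- deviation_series(tr, sched)
  expect_equal(dev$segment[dev$time_s == 100 + 1800], 2L)
  expect_equal(dev$segment[dev$time_s == 100 + 1798], 1L)
})

test_that("a significant tidal shift across a bout splits the segment", {
  # depth steps up 0.4 m across a 60 s excursion; s.d. ~ 0.01 so the step is
  # far beyond 3 sigma and the mid-movement recalculation must fire
  set.seed(7)
  dt <- 2
  n <- 1200 # 2400 s
  depths <- rep(8, n) + rnorm(n, 0, 0.01)
  t_all <- seq(0, by = dt, length.out = n)
  bout <- t_all >= 1000 & t_all < 1060
  depths[bout] <- depths[bout] - 0.5
  depths[t_all >= 1060] <- depths[t_all >= 1060] + 0.4
  tr <- depth_trace(t_all, depths, sample_interval_s = dt)
  sched <- build_baseline_schedule(tr, 100, 2200, gear)
  expect_true("tidal-recalc" %in% sched$source)
  k <- which(sched$source == "tidal-recalc")
  # recalculated baseline averages the 1-min windows flanking the movement
  expect_equal(sched$baseline_depth_m[k], 8.2, tolerance = 0.05)
  expect_equal(sched$start_s[k], 1060, tolerance = 10)
  # downstream of the split nothing reads as movement any more
  dev <- deviation_series(tr, sched)
  b <- detect_bouts(dev, 0.5, gear)
  expect_true(all(b$end_s <= sched$start_s[k] + 10))
})
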