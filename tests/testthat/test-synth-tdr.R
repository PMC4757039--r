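gear <- gear_config()

test_that("a degenerate scenario gives constant depth then a monotone haul ramp", {
  sc <- trace_scenario(swell_sd_m = 0, tide_amplitude_m = 0,
                       capture_time_s = 600, capture_duration_min = 30,
                       initial_bout_duration_s = 0, bout_rate_per_h = 0)
  st <- simulate_trace(sc)
  tr <- st$trace
  pre <- tr$depths[tr$times < st$truth$haul_time_s]
  expect_true(all(pre == 8))
  ramp <- tr$depths[tr$times >= st$truth$haul_time_s &
                      tr$times <= st$truth$haul_time_s + sc$haul_ramp_s]
  expect_true(all(diff(ramp) <= 0))
  expect_equal(tr$depths[length(tr$depths)], 0)
  expect_equal(st$truth$movement$movement_pct, c(0, 0))
})

test_that("a single 600 s bout of full amplitude in a 6000 s capture is 10% movement", {
  sc <- trace_scenario(swell_sd_m = 0, tide_amplitude_m = 0,
                       capture_time_s = 600, capture_duration_min = 100,
                       initial_bout_duration_s = 0,
                       bouts = data.frame(start_s = 2000, duration_s = 600,
                                          amplitude_m = 0.6))
  st <- simulate_trace(sc)
  tru <- st$truth$movement
  expect_equal(tru$movement_pct[tru$threshold_fraction == 0.5], 10)
  # at full extension only the plateau (duration minus both edges) qualifies
  expect_equal(tru$movement_s[tru$threshold_fraction == 1], 600 - 2 * sc$edge_s)
})

test_that("simulation is deterministic under a seed, as are cohorts", {
  a <- simulate_trace(trace_scenario(seed = 77))
  b <- simulate_trace(trace_scenario(seed = 77))
  expect_identical(a$trace$depths, b$trace$depths)
  expect_identical(a$truth$movement, b$truth$movement)
  ca <- simulate_cohort(3, seed = 13)
  cb <- simulate_cohort(3, seed = 13)
  expect_identical(lapply(ca, function(x) x$trace$depths),
                   lapply(cb, function(x) x$trace$depths))
})

test_that("cohorts honour their size and stated ranges", {
  co <- simulate_cohort(13, seed = 31)
  expect_length(co, 13L)
  durs <- vapply(co, function(x) x$truth$capture_duration_min, numeric(1))
  expect_true(all(durs >= 31.7 - 1 & durs <= 219.7 + 1))
  for (ct in co) {
    expect_true(all(ct$truth$bouts$amplitude_m <= gear$effective_extension_m + 1e-9))
    b <- ct$truth$bouts
    expect_true(all(b$start_s >= ct$truth$capture_time_s))
    expect_true(all(b$end_s <= ct$truth$haul_time_s))
    expect_true(all(diff(b$start_s) > 0))
  }
})

test_that("the pipeline recovers capture duration and movement from simulated traces", {
  # swell-isolation design: tide held at zero so the target of the check is
  # the detector's response to swell noise alone
  co <- simulate_cohort(20, seed = 41, tide_amplitude_m = 0)
  for (ct in co) {
    res <- analyze_trace(ct$trace, gear, haul_time_s = ct$truth$haul_time_s)
    expect_lte(abs(res$capture$capture_time_s - ct$truth$capture_time_s),
               2 * ct$trace$sample_interval_s)
    det <- res$summary$movement
    tru <- ct$truth$movement
    expect_lte(abs(det$movement_pct[det$threshold_fraction == 0.5] -
                     tru$movement_pct[tru$threshold_fraction == 0.5]), 1)
  }
})

test_that("under the default tide the detector stays unbiased and ordered", {
  co <- simulate_cohort(25, seed = 42) # defaults: tide amplitude 0.5 m
  errs <- vapply(co, function(ct) {
    res <- analyze_trace(ct$trace, gear, haul_time_s = ct$truth$haul_time_s)
    det <- res$summary$movement
    tru <- ct$truth$movement
    p50 <- det$movement_pct[det$threshold_fraction == 0.5]
    p100 <- det$movement_pct[det$threshold_fraction == 1]
    expect_gte(p50, p100) # threshold ordering on every trace
    p50 - tru$movement_pct[tru$threshold_fraction == 0.5]
  }, numeric(1))
  expect_lte(abs(mean(errs)), 0.5)
  expect_lte(max(abs(errs)), 2.5) # tidal drift widens the per-trace envelope
})

test_that("re-analysing a serialised trace reproduces the summary bit-for-bit", {
  st <- simulate_trace(trace_scenario(seed = 55, capture_duration_min = 60))
  res1 <- analyze_trace(st$trace, gear)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trace(st$trace, tf)
  res2 <- analyze_trace(read_trace(tf, device_id = st$trace$device_id), gear)
  expect_identical(as.data.frame(res1$summary), as.data.frame(res2$summary))
})
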