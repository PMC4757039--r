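fast_mcmc <- function(seed = NULL, ...) {
  mcmc_config(iterations = 6000, burn_in = 1000, thinning = 5, seed = seed, ...)
}

test_that("the CI significance rule matches its defining cases", {
  expect_false(significance(-52.285, 52.725))
  expect_true(significance(-1.528, -0.550))
  expect_false(significance(0, 1)) # zero included -> not significant
  expect_true(significance(0.001, 1))
  expect_equal(significance(c(-1, 2), c(1, 3)), c(FALSE, TRUE))
  expect_error(significance(1, 0), "must not exceed")
})

test_that("a known additive model is recovered: null duration, real SST effect", {
  set.seed(10)
  n <- 200
  dur <- runif(n, 32, 241)
  sst <- runif(n, 12, 20)
  y <- 2 + 0 * dur + 0.2 * sst + rnorm(n, 0, 0.5)
  rec <- data.frame(capture_duration_min = dur, sst_c = sst, glucose = y,
                    alive = TRUE)
  fit <- fit_additive_regression(rec, "glucose", mcmc = fast_mcmc(seed = 1))
  co <- fit$coefficients
  d <- co[co$term == "capture_duration_min", ]
  s <- co[co$term == "sst_c", ]
  expect_false(d$significant)
  expect_true(d$ci_2.5 <= 0 && 0 <= d$ci_97.5)
  expect_true(s$significant)
  expect_equal(s$mean, 0.2, tolerance = 0.1)
})

test_that("noise-free planar data is reproduced to 1e-6 relative error", {
  set.seed(11)
  n <- 20
  dur <- runif(n, 0, 4)
  sst <- runif(n, -2, 2)
  y <- 1.5 - 0.3 * dur + 0.8 * sst # exact plane
  rec <- data.frame(capture_duration_min = dur, sst_c = sst, pH = y,
                    alive = TRUE)
  # the zero-noise limit needs a near-improper variance prior: any fixed
  # inverse-gamma rate floors sigma^2 and hence the Monte-Carlo error
  fit <- suppressWarnings(fit_additive_regression(
    rec, "pH",
    mcmc = mcmc_config(iterations = 6000, burn_in = 1000, thinning = 5,
                       residual_rate = 1e-12, seed = 2)
  ))
  truth <- c(1.5, -0.3, 0.8)
  expect_equal(fit$coefficients$mean, truth, tolerance = 1e-6)
})

test_that("with fixed residual variance the sampler matches the conjugate closed form", {
  set.seed(12)
  n <- 40
  X <- cbind(1, runif(n, -1, 1), runif(n, -1, 1))
  colnames(X) <- c("b0", "b1", "b2")
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n, 0, 0.7)
  sigma2 <- 0.49
  mc <- mcmc_config(iterations = 21000, burn_in = 1000, thinning = 2, seed = 3)
  draws <- gibbs_lm(X, y, mc, fixed_sigma2 = sigma2)
  ref <- conjugate_posterior(X, y, sigma2, mc$prior_precision)
  m <- nrow(draws$beta)
  for (j in 1:3) {
    mc_se <- ref$sd[j] / sqrt(m)
    expect_lt(abs(mean(draws$beta[, j]) - ref$mean[j]), 3 * mc_se * 3)
    expect_equal(stats::sd(draws$beta[, j]), unname(ref$sd[j]), tolerance = 0.1)
  }
})

test_that("fits are deterministic under a seed and reject degenerate input", {
  cohort <- generate_cohort(blood_scenario(n = 20, seed = 5))
  f1 <- fit_additive_regression(cohort, "glucose", mcmc = fast_mcmc(seed = 9))
  f2 <- fit_additive_regression(cohort, "glucose", mcmc = fast_mcmc(seed = 9))
  expect_identical(f1$coefficients, f2$coefficients)

  dead <- cohort
  dead$alive <- FALSE
  expect_error(
    fit_additive_regression(dead, "glucose", mcmc = fast_mcmc()),
    "at least 4 live"
  )
  const <- cohort
  const$sst_c <- 16
  expect_error(
    fit_additive_regression(const, "glucose", mcmc = fast_mcmc()),
    "constant predictor"
  )
})

test_that("dead animals are dropped before fitting", {
  cohort <- generate_cohort(blood_scenario(n = 24, seed = 6))
  cohort$alive[1:2] <- FALSE
  expect_message(
    fit <- fit_additive_regression(cohort, "glucose", mcmc = fast_mcmc(seed = 1)),
    "excluding 2 dead"
  )
  expect_equal(fit$n, 22L)
})

test_that("predicted means respect slopes, transforms and extrapolation bounds", {
  set.seed(13)
  n <- 60
  dur <- runif(n, 32, 241)
  sst <- runif(n, 12, 20)

  # identity: slope 0 -> prediction equals the intercept everywhere
  rec0 <- data.frame(capture_duration_min = dur, sst_c = sst,
                     glucose = 5 + rnorm(n, 0, 1e-8), alive = TRUE)
  f0 <- suppressWarnings(
    fit_additive_regression(rec0, "glucose", mcmc = fast_mcmc(seed = 4))
  )
  pr0 <- predict_mean(f0, c(12, 20))
  expect_equal(pr0$mean, c(5, 5), tolerance = 1e-3)

  # log transform: the 20 vs 12 degC prediction ratio is exp(8 * slope)
  lac <- exp(-1.5 + 0.221 * sst + rnorm(n, 0, 1e-8))
  rec1 <- data.frame(capture_duration_min = dur, sst_c = sst, lactate = lac,
                     alive = TRUE)
  f1 <- suppressWarnings(
    fit_additive_regression(rec1, "lactate", mcmc = fast_mcmc(seed = 5))
  )
  pr1 <- predict_mean(f1, c(12, 20))
  expect_equal(pr1$mean[2] / pr1$mean[1], exp(0.221 * 8), tolerance = 1e-3)
  # transform round-trip against the noiseless generating curve, <= 0.1%
  ssts <- seq(12, 20, by = 2)
  pr <- predict_mean(f1, ssts)
  expect_equal(pr$mean, exp(-1.5 + 0.221 * ssts), tolerance = 1e-3)

  expect_warning(predict_mean(f1, 25), "extrapolates")
})

test_that("slope posteriors contract as the sample grows", {
  sds <- vapply(c(20, 200, 2000), function(n) {
    cohort <- generate_cohort(blood_scenario(n = n, seed = 7))
    fit <- fit_additive_regression(cohort, "glucose", mcmc = fast_mcmc(seed = 8))
    fit$coefficients$sd[fit$coefficients$term == "sst_c"]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("two-group estimation flags separated groups and not identical ones", {
  set.seed(14)
  x <- rnorm(40)
  same <- two_group_difference(x, x, fast_mcmc(seed = 1))
  expect_false(same$significant)
  expect_true(same$ci_2.5 <= 0 && 0 <= same$ci_97.5)

  a <- rnorm(50, 0, 1)
  b <- rnorm(50, 5, 1)
  diffed <- two_group_difference(a, b, fast_mcmc(seed = 2))
  expect_true(diffed$significant)
  mc_se <- sqrt(2 / 50)
  expect_equal(diffed$mu, mean(a) - mean(b), tolerance = 3 * mc_se)
  expect_equal(diffed$mu, -5, tolerance = 3 * mc_se + 3 * sqrt(2 / 50))

  expect_error(two_group_difference(1, c(1, 2)), "n >= 2")
  expect_warning(two_group_difference(c(1, 1, 1), c(1, 2, 3), fast_mcmc(seed = 3)),
                 "zero variance")
})

test_that("effective size is sane on white noise and flags sticky chains", {
  set.seed(15)
  w <- rnorm(2000)
  expect_gt(effective_size(w), 1000)
  sticky <- as.numeric(stats::filter(rnorm(2000), 0.99, "recursive"))
  expect_lt(effective_size(sticky), 200)
})

test_that("the quadratic screen finds no curvature in linear data", {
  set.seed(16)
  n <- 80
  dur <- runif(n, 32, 241)
  sst <- runif(n, 12, 20)
  rec <- data.frame(capture_duration_min = dur, sst_c = sst,
                    glucose = 2 + 0.2 * sst + rnorm(n, 0, 0.6), alive = TRUE)
  quad <- check_linearity(rec, "glucose", mcmc = fast_mcmc(seed = 6))
  expect_equal(nrow(quad), 2L)
  expect_false(any(quad$significant))
})
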