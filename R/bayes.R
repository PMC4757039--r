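# Bayesian additive linear regression by Gibbs sampling, posterior prediction,
# credibility-interval significance and BEST-style two-group estimation.

#' MCMC settings
#'
#' @param iterations Total Gibbs iterations. Default 50000.
#' @param burn_in Iterations discarded before retention. Default 2000.
#' @param thinning Retain every `thinning`-th post-burn-in draw. Default 10.
#' @param prior_precision Precision of the zero-mean normal prior on every
#'   regression coefficient. The default 1e-6 is the conventional vague
#'   choice (prior s.d. 1000).
#' @param residual_shape,residual_rate Shape/rate of the vague inverse-gamma
#'   prior on the residual variance. Defaults 1e-3, 1e-3.
#' @param seed Seed applied before sampling (NULL leaves the RNG state alone).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 50000, burn_in = 2000, thinning = 10,
                        prior_precision = 1e-6,
                        residual_shape = 1e-3, residual_rate = 1e-3,
                        seed = NULL) {
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (thinning < 1) stop("thinning must be >= 1")
  if (prior_precision <= 0) stop("prior_precision must be > 0")
  structure(
    list(iterations = iterations, burn_in = burn_in, thinning = thinning,
         prior_precision = prior_precision,
         residual_shape = residual_shape, residual_rate = residual_rate,
         seed = seed),
    class = "mcmc_config"
  )
}

#' Gibbs sampler for the normal linear model
#'
#' Samples the posterior of `y = X b + e`, `e ~ N(0, sigma2)`, under
#' independent `N(0, 1/prior_precision)` priors on the coefficients and an
#' inverse-gamma prior on `sigma2`. Exposed mainly so tests can exercise the
#' conjugate closed form (fix `sigma2` and the coefficient posterior is exact
#' multivariate normal).
#'
#' @param X Design matrix (n x p).
#' @param y Response vector.
#' @param mcmc An [mcmc_config()].
#' @param fixed_sigma2 When non-NULL the residual variance is held at this
#'   value instead of being sampled.
#' @return List with `beta` (retained draws, m x p) and `sigma` (residual
#'   s.d. draws, length m).
#' @export
gibbs_lm <- function(X, y, mcmc = mcmc_config(), fixed_sigma2 = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  tau <- mcmc$prior_precision
  a0 <- mcmc$residual_shape
  b0 <- mcmc$residual_rate
  sigma2 <- if (is.null(fixed_sigma2)) max(stats::var(y), 1e-8) else fixed_sigma2
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  beta_draws <- matrix(NA_real_, n_keep, p)
  sigma_draws <- numeric(n_keep)
  Ip <- diag(tau, p)
  k <- 0L
  for (it in seq_len(mcmc$iterations)) {
    prec <- XtX / sigma2 + Ip
    U <- chol(prec)
    mu <- backsolve(U, forwardsolve(t(U), Xty / sigma2))
    beta <- mu + backsolve(U, stats::rnorm(p))
    if (is.null(fixed_sigma2)) {
      rss <- sum((y - X %*% beta)^2)
      sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, rate = b0 + rss / 2)
    }
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
      k <- k + 1L
      beta_draws[k, ] <- beta
      sigma_draws[k] <- sqrt(sigma2)
    }
  }
  colnames(beta_draws) <- colnames(X)
  list(beta = beta_draws, sigma = sigma_draws)
}

#' Effective sample size of a chain
#'
#' Geyer's initial positive sequence estimator on the sample
#' autocorrelations: sums consecutive even/odd autocorrelation pairs until a
#' pair turns negative.
#'
#' @param x Numeric vector of (thinned) posterior draws.
#' @return Estimated effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Credibility-interval significance rule
#'
#' A quantity is deemed significant when its 2.5-97.5% credibility interval
#' does not cross or include zero.
#'
#' @param ci_lo,ci_hi Interval bounds (vectorised).
#' @return Logical: `ci_lo > 0 | ci_hi < 0`. An interval touching zero at
#'   either end includes it and is not significant.
#' @examples
#' significance(-52.285, 52.725) # FALSE
#' significance(-1.528, -0.550)  # TRUE
#' significance(0, 1)            # FALSE
#' @export
significance <- function(ci_lo, ci_hi) {
  if (any(ci_lo > ci_hi)) stop("ci_lo must not exceed ci_hi")
  ci_lo > 0 | ci_hi < 0
}

.summarise_draws <- function(draws) {
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(
    term = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    ci_2.5 = qs[1L, ],
    ci_97.5 = qs[2L, ],
    significant = significance(qs[1L, ], qs[2L, ]),
    row.names = NULL
  )
}

#' Bayesian additive linear regression of a blood variable
#'
#' Fits `response ~ capture_duration_min + sst_c` (optionally with their
#' interaction) by Gibbs sampling under vague priors. Lactate (or any
#' variable whose `transform` is `"log"`) is natural-log transformed before
#' fitting. Dead animals (`alive == FALSE`) are excluded, mirroring the
#' field protocol of dropping moribund individuals from regression.
#'
#' @param records Data frame of blood records with columns
#'   `capture_duration_min`, `sst_c`, `alive` and the response variable.
#' @param response Name of the response column.
#' @param include_interaction Add a `duration x SST` term. Default FALSE (no
#'   interaction was supported by the data this models).
#' @param mcmc An [mcmc_config()].
#' @param transform `"identity"` or `"log"`; defaults to `"log"` for
#'   lactate and `"identity"` otherwise.
#' @return Object of class `posterior_summary`: coefficient table (posterior
#'   mean, s.d., 2.5/97.5% bounds, significance flag), residual-s.d. summary,
#'   retained draws, transform tag and convergence diagnostics (effective
#'   sample sizes and a split-chain mean-stability check).
#' @export
fit_additive_regression <- function(records, response,
                                    include_interaction = FALSE,
                                    mcmc = mcmc_config(),
                                    transform = NULL) {
  records <- as.data.frame(records)
  needed <- c(response, "capture_duration_min", "sst_c")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records lack column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if ("alive" %in% names(records)) {
    n_dead <- sum(!records$alive)
    if (n_dead > 0) {
      message(sprintf("excluding %d dead animal(s) from the regression", n_dead))
    }
    records <- records[as.logical(records$alive), , drop = FALSE]
  }
  records <- records[stats::complete.cases(records[needed]), , drop = FALSE]
  if (nrow(records) < 4L) stop("need at least 4 live records with complete data")
  if (is.null(transform)) {
    transform <- if (identical(response, "lactate")) "log" else "identity"
  }
  y <- records[[response]]
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires strictly positive responses")
    y <- log(y)
  }
  X <- cbind(
    intercept = 1,
    capture_duration_min = records$capture_duration_min,
    sst_c = records$sst_c
  )
  if (include_interaction) {
    X <- cbind(X, `duration:sst` = records$capture_duration_min * records$sst_c)
  }
  sds <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant predictor: %s", names(sds)[sds == 0][1L]))
  }
  if (kappa(qr.R(qr(scale(X[, -1L, drop = FALSE])))) > 1e8) {
    stop("predictors are (near-)collinear")
  }
  draws <- gibbs_lm(X, y, mcmc)
  coefs <- .summarise_draws(draws$beta)
  ess <- apply(draws$beta, 2L, effective_size)
  half <- nrow(draws$beta) %/% 2L
  split_z <- vapply(seq_len(ncol(draws$beta)), function(j) {
    a <- draws$beta[seq_len(half), j]
    b <- draws$beta[seq.int(half + 1L, 2L * half), j]
    abs(mean(a) - mean(b)) / stats::sd(draws$beta[, j])
  }, numeric(1L))
  diagnostics <- data.frame(term = coefs$term, ess = ess, split_z = split_z)
  converged <- all(ess >= 200) && all(split_z < 0.2)
  if (!converged) {
    warning("convergence diagnostics failed (low effective sample size or unstable chain halves)")
  }
  structure(
    list(
      response = response,
      transform = transform,
      coefficients = coefs,
      sigma = c(mean = mean(draws$sigma),
                ci_2.5 = unname(stats::quantile(draws$sigma, 0.025)),
                ci_97.5 = unname(stats::quantile(draws$sigma, 0.975))),
      draws = draws,
      n = nrow(records),
      diagnostics = diagnostics,
      converged = converged,
      mcmc = mcmc
    ),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Bayesian additive regression: %s%s (n = %d%s)\n",
              x$response,
              if (x$transform == "log") " (log scale)" else "",
              x$n,
              if (x$converged) "" else "; diagnostics FAILED"))
  df <- x$coefficients
  df$mean <- signif(df$mean, 4)
  df$sd <- signif(df$sd, 4)
  df$ci_2.5 <- signif(df$ci_2.5, 4)
  df$ci_97.5 <- signif(df$ci_97.5, 4)
  df$significant <- ifelse(df$significant, "*", "")
  print(df, row.names = FALSE)
  cat(sprintf("residual s.d.: %.4g (%.4g, %.4g)\n",
              x$sigma["mean"], x$sigma["ci_2.5"], x$sigma["ci_97.5"]))
  invisible(x)
}

#' Posterior predicted mean at given SST and capture duration
#'
#' Evaluates the linear predictor for every retained posterior draw at the
#' requested covariates; for log-transformed responses each draw is
#' exponentiated back to the response scale before summarising (posterior
#' mean of the back-transform, not the back-transform of the mean).
#'
#' @param fit A `posterior_summary` from [fit_additive_regression()].
#' @param sst_c Sea-surface temperature(s) at which to predict (vectorised).
#' @param duration_min Capture duration (min) to standardise at; default 0.
#' @param sst_bounds SSTs outside this range trigger an extrapolation
#'   warning (not an error). Default `c(12, 20)`, the range the defaults were
#'   calibrated over.
#' @return Data frame with columns `sst_c`, `duration_min`, `mean`,
#'   `ci_2.5`, `ci_97.5`.
#' @export
predict_mean <- function(fit, sst_c, duration_min = 0, sst_bounds = c(12, 20)) {
  stopifnot(inherits(fit, "posterior_summary"))
  if (!fit$converged) {
    warning("predicting from a fit whose convergence diagnostics failed")
  }
  if (any(sst_c < sst_bounds[1L] | sst_c > sst_bounds[2L])) {
    warning("prediction extrapolates beyond the configured SST bounds")
  }
  b <- fit$draws$beta
  out <- lapply(sst_c, function(s) {
    eta <- b[, "intercept"] + b[, "capture_duration_min"] * duration_min +
      b[, "sst_c"] * s
    if ("duration:sst" %in% colnames(b)) {
      eta <- eta + b[, "duration:sst"] * duration_min * s
    }
    if (fit$transform == "log") eta <- exp(eta)
    data.frame(
      sst_c = s, duration_min = duration_min,
      mean = mean(eta),
      ci_2.5 = unname(stats::quantile(eta, 0.025)),
      ci_97.5 = unname(stats::quantile(eta, 0.975))
    )
  })
  do.call(rbind, out)
}

#' BEST-style Bayesian two-group difference
#'
#' Estimates the difference in means between two groups under independent
#' normal likelihoods with group-specific variances and vague priors (a
#' normal-model simplification of Bayesian estimation-supersedes-the-t-test).
#' Significance follows the credibility-interval rule.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param mcmc An [mcmc_config()].
#' @return Object of class `group_difference`: `mu` (posterior mean of
#'   mean(a) - mean(b)), `ci_2.5`, `ci_97.5`, `significant`, plus per-group
#'   posterior mean summaries and the difference draws.
#' @export
two_group_difference <- function(a, b, mcmc = mcmc_config()) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("a group has zero variance; the prior regularises its variance")
  }
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  sample_group <- function(y) {
    n <- length(y)
    tau <- mcmc$prior_precision
    a0 <- mcmc$residual_shape
    b0 <- mcmc$residual_rate
    sigma2 <- max(stats::var(y), 1e-8)
    mu <- mean(y)
    n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
    mu_draws <- numeric(n_keep)
    k <- 0L
    for (it in seq_len(mcmc$iterations)) {
      prec <- n / sigma2 + tau
      mu <- stats::rnorm(1, (sum(y) / sigma2) / prec, sqrt(1 / prec))
      rss <- sum((y - mu)^2)
      sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, rate = b0 + rss / 2)
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
        k <- k + 1L
        mu_draws[k] <- mu
      }
    }
    mu_draws
  }
  mu_a <- sample_group(a)
  mu_b <- sample_group(b)
  d <- mu_a - mu_b
  lo <- unname(stats::quantile(d, 0.025))
  hi <- unname(stats::quantile(d, 0.975))
  structure(
    list(
      mu = mean(d), ci_2.5 = lo, ci_97.5 = hi,
      significant = significance(lo, hi),
      group_means = data.frame(
        group = c("a", "b"),
        mean = c(mean(mu_a), mean(mu_b)),
        sd = c(stats::sd(mu_a), stats::sd(mu_b))
      ),
      draws = d
    ),
    class = "group_difference"
  )
}

#' @export
print.group_difference <- function(x, ...) {
  cat(sprintf(
    "Bayesian two-group difference: mu = %.3f, CI[2.5, 97.5] = (%.3f, %.3f)%s\n",
    x$mu, x$ci_2.5, x$ci_97.5, if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Linear-versus-quadratic screen for non-linearity
#'
#' A light-weight stand-in for an exploratory additive-model screen: refits
#' the additive regression with squared duration and SST terms appended and
#' reports whether either quadratic coefficient is significant by the CI
#' rule. Non-significant quadratic terms justify staying with the additive
#' linear model.
#'
#' @inheritParams fit_additive_regression
#' @return Data frame with one row per quadratic term: posterior mean, CI
#'   bounds and significance flag.
#' @export
check_linearity <- function(records, response, mcmc = mcmc_config(),
                            transform = NULL) {
  records <- as.data.frame(records)
  if ("alive" %in% names(records)) {
    records <- records[as.logical(records$alive), , drop = FALSE]
  }
  if (is.null(transform)) {
    transform <- if (identical(response, "lactate")) "log" else "identity"
  }
  y <- records[[response]]
  if (transform == "log") y <- log(y)
  d <- records$capture_duration_min
  s <- records$sst_c
  # centre before squaring to decorrelate the quadratic terms
  X <- cbind(
    intercept = 1, duration = d, sst = s,
    duration2 = (d - mean(d))^2, sst2 = (s - mean(s))^2
  )
  draws <- gibbs_lm(X, y, mcmc)
  out <- .summarise_draws(draws$beta)
  out[out$term %in% c("duration2", "sst2"), , drop = FALSE]
}
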