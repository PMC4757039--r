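# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain per-sample loops and closed forms.

# brute-force bout detector: walk every sample, label supra-threshold points,
# close a bout only when the sub-threshold gap exceeds gap_s
brute_force_bouts <- function(deviation, threshold, dt, gap_s) {
  supra <- deviation >= threshold
  out <- list()
  cur_start <- NA_integer_
  last_supra <- NA_integer_
  for (i in seq_along(supra)) {
    if (!supra[i]) next
    if (is.na(cur_start)) {
      cur_start <- i
    } else if ((i - last_supra - 1L) * dt > gap_s) {
      out[[length(out) + 1L]] <- c(cur_start, last_supra)
      cur_start <- i
    }
    last_supra <- i
  }
  if (!is.na(cur_start)) out[[length(out) + 1L]] <- c(cur_start, last_supra)
  if (length(out) == 0L) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start_idx = m[, 1L], end_idx = m[, 2L])
}

# closed-form coefficient posterior for the normal linear model with KNOWN
# residual variance and N(0, 1/tau) coefficient priors
conjugate_posterior <- function(X, y, sigma2, tau) {
  V <- solve(crossprod(X) / sigma2 + diag(tau, ncol(X)))
  m <- V %*% (crossprod(X, y) / sigma2)
  list(mean = drop(m), sd = sqrt(diag(V)))
}

# constant-depth trace with optional added vector of perturbations
make_flat_trace <- function(n, depth = 8, dt = 2, add = 0) {
  depth_trace(seq(0, by = dt, length.out = n), rep(depth, n) + add,
              device_id = "TEST", sample_interval_s = dt)
}

# deviation data frame wired up by hand (single segment covering everything)
make_dev <- function(deviation, sd_m = 0, dt = 2) {
  out <- data.frame(
    time_s = seq(0, by = dt, length.out = length(deviation)),
    depth_m = NA_real_,
    segment = 1L,
    baseline_depth_m = NA_real_,
    baseline_sd_m = sd_m
  )
  out$deviation_m <- deviation
  attr(out, "sample_interval_s") <- dt
  out
}
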