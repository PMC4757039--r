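# Capture-point detection, movement-bout detection and per-capture summary.

.trailing_stats <- function(depths, n_w) {
  # trailing-window mean/sd for window (i - n_w) .. (i - 1), defined for i > n_w
  n <- length(depths)
  cs <- cumsum(depths)
  cs2 <- cumsum(depths^2)
  i <- seq.int(n_w + 1L, n)
  s <- cs[i - 1L] - c(0, cs)[i - n_w]
  s2 <- cs2[i - 1L] - c(0, cs2)[i - n_w]
  m <- s / n_w
  v <- pmax(0, (s2 - n_w * m^2) / (n_w - 1L))
  list(idx = i, mean = m, sd = sqrt(v))
}

#' Detect the capture point of a depth trace
#'
#' The capture point is the initial marked depth change: the first sample
#' whose absolute deviation from the trailing 1-min steady baseline meets or
#' exceeds the lowest-fraction movement threshold (fraction x effective
#' extension + trailing-window s.d.) and does so for at least
#' `capture_min_run_samples` consecutive samples. Single-sample swell spikes
#' are thereby ignored.
#'
#' @param trace A [depth_trace()].
#' @param gear A [gear_config()].
#' @return A list of class `capture_point`: `detected` (logical),
#'   `capture_time_s`, `capture_depth_m` (the trailing baseline depth at the
#'   capture point), `index`. When no exceedance exists anywhere the sentinel
#'   `detected = FALSE` is returned (not an error).
#' @export
detect_capture_point <- function(trace, gear = gear_config()) {
  stopifnot(inherits(trace, "depth_trace"))
  dt <- trace$sample_interval_s
  n_w <- max(2L, round(gear$baseline_window_s / dt))
  if (length(trace) < 2L * n_w) {
    stop("trace shorter than twice the baseline window")
  }
  tw <- .trailing_stats(trace$depths, n_w)
  frac <- min(gear$threshold_fractions) * gear$effective_extension_m
  dev <- abs(trace$depths[tw$idx] - tw$mean)
  thr <- frac + tw$sd
  # candidate onsets exceed the threshold against their own trailing window;
  # persistence is then checked against the baseline *frozen at the onset*
  # (the trailing window would otherwise swallow the excursion itself)
  candidates <- which(dev >= thr)
  m_run <- gear$capture_min_run_samples
  n <- length(trace$depths)
  anchor <- NA_integer_
  for (k in candidates) {
    # candidates within one window of the episode onset reuse its clean
    # baseline; their own trailing windows already contain the excursion
    if (is.na(anchor) || k - anchor >= n_w) anchor <- k
    idx <- tw$idx[k]
    if (idx + m_run - 1L > n) break
    seg <- trace$depths[idx:(idx + m_run - 1L)]
    if (all(abs(seg - tw$mean[anchor]) >= frac + tw$sd[anchor])) {
      return(structure(
        list(
          detected = TRUE,
          capture_time_s = trace$times[idx],
          capture_depth_m = tw$mean[anchor],
          index = idx
        ),
        class = "capture_point"
      ))
    }
  }
  structure(
    list(detected = FALSE, capture_time_s = NA_real_,
         capture_depth_m = NA_real_, index = NA_integer_),
    class = "capture_point"
  )
}

#' @export
print.capture_point <- function(x, ...) {
  if (!x$detected) {
    cat("<capture_point: no capture detected>\n")
  } else {
    cat(sprintf("<capture_point: t = %.0f s, baseline depth %.2f m>\n",
                x$capture_time_s, x$capture_depth_m))
  }
  invisible(x)
}

#' Auto-detect the haul (gear-up) point
#'
#' The haul point in the field is visually determined and checked against the
#' landing time; when it is not supplied explicitly this helper locates the
#' first monotone ascent that carries the trace to less than
#' `surface_threshold_m` depth after the capture point and returns the start
#' of that ramp. The trace is median-smoothed (window of 5 samples) so swell
#' does not fragment the ramp.
#'
#' @param trace A [depth_trace()].
#' @param capture_time_s Capture time (s).
#' @param surface_threshold_m Depth regarded as "at the surface" (default 1 m).
#' @return Haul time (s from trace start). If the trace never surfaces the
#'   last sample time is returned with a warning.
#' @export
detect_haul_point <- function(trace, capture_time_s, surface_threshold_m = 1) {
  stopifnot(inherits(trace, "depth_trace"))
  sm <- stats::runmed(trace$depths, 5)
  c_idx <- findInterval(capture_time_s, trace$times)
  after <- which(sm < surface_threshold_m & seq_along(sm) > c_idx)
  if (length(after) == 0L) {
    warning("trace never reaches the surface after capture; using trace end as haul point")
    return(trace$times[length(trace$times)])
  }
  j <- after[1L]
  while (j > c_idx + 1L && sm[j - 1L] > sm[j] + 1e-9) j <- j - 1L
  trace$times[j]
}

# maximal supra-threshold runs with gaps <= gap_s bridged; returns a matrix
# of (start_idx, end_idx) pairs into the logical vector
.bridged_runs <- function(supra, dt, gap_s) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(matrix(integer(0), ncol = 2L))
  out <- matrix(c(starts[keep[1L]], ends[keep[1L]]), ncol = 2L)
  if (length(keep) > 1L) {
    for (k in keep[-1L]) {
      gap_samples <- starts[k] - out[nrow(out), 2L] - 1L
      if (gap_samples * dt <= gap_s) {
        out[nrow(out), 2L] <- ends[k]
      } else {
        out <- rbind(out, c(starts[k], ends[k]))
      }
    }
  }
  out
}

#' Detect movement bouts from a deviation series
#'
#' Step 4: movement is confirmed where the absolute deviation meets or
#' exceeds the threshold at the given fraction (per covering segment), and is
#' deemed to have ceased only when the threshold goes unmet for more than
#' `cessation_gap_s` seconds. Shorter sub-threshold gaps are bridged and the
#' gap samples count as movement. Each sample covers `[t, t + dt)`, so a bout
#' ends one sampling step after its last supra-threshold sample.
#'
#' @param deviations Output of [deviation_series()].
#' @param fraction Threshold fraction (one of `gear$threshold_fractions`).
#' @param gear A [gear_config()].
#' @return Data frame of disjoint bouts sorted by time: `start_s`, `end_s`,
#'   `duration_s`, `peak_deviation_m`, `threshold_fraction`.
#' @export
detect_bouts <- function(deviations, fraction, gear = gear_config()) {
  dt <- attr(deviations, "sample_interval_s")
  if (is.null(dt)) stop("deviations lack a sample_interval_s attribute")
  thr <- fraction * gear$effective_extension_m + deviations$baseline_sd_m
  supra <- deviations$deviation_m >= thr
  runs <- .bridged_runs(supra, dt, gear$cessation_gap_s)
  if (nrow(runs) == 0L) {
    return(data.frame(
      start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
      peak_deviation_m = numeric(0), threshold_fraction = numeric(0)
    ))
  }
  start_s <- deviations$time_s[runs[, 1L]]
  end_s <- deviations$time_s[runs[, 2L]] + dt
  peak <- vapply(
    seq_len(nrow(runs)),
    function(i) max(deviations$deviation_m[runs[i, 1L]:runs[i, 2L]]),
    numeric(1L)
  )
  data.frame(
    start_s = start_s, end_s = end_s, duration_s = end_s - start_s,
    peak_deviation_m = peak, threshold_fraction = fraction
  )
}

#' Summarise a capture
#'
#' Step 5 bookkeeping: capture duration in minutes and, per threshold
#' fraction, total movement time and the percentage of the capture spent
#' moving.
#'
#' @param trace A [depth_trace()].
#' @param capture_time_s,haul_time_s Capture window bounds (s).
#' @param bouts_by_fraction Named list of bout data frames (names are the
#'   threshold fractions, e.g. `"0.5"`), as from [detect_bouts()].
#' @param capture_depth_m Baseline depth at capture (optional, for reporting).
#' @return Object of class `capture_summary`.
#' @export
summarize_capture <- function(trace, capture_time_s, haul_time_s,
                              bouts_by_fraction, capture_depth_m = NA_real_) {
  if (haul_time_s <= capture_time_s) stop("haul_time_s must exceed capture_time_s")
  duration_min <- (haul_time_s - capture_time_s) / 60
  rows <- lapply(names(bouts_by_fraction), function(f) {
    b <- bouts_by_fraction[[f]]
    if (nrow(b) > 0 &&
        (min(b$start_s) < capture_time_s - 1e-9 ||
         max(b$end_s) > haul_time_s + 1e-9)) {
      stop("bouts extend outside [capture_time_s, haul_time_s]")
    }
    mv_min <- sum(b$duration_s) / 60
    data.frame(
      threshold_fraction = as.numeric(f),
      n_bouts = nrow(b),
      movement_min = mv_min,
      movement_pct = 100 * mv_min / duration_min
    )
  })
  movement <- do.call(rbind, rows)
  movement <- movement[order(movement$threshold_fraction), , drop = FALSE]
  rownames(movement) <- NULL
  if (any(movement$movement_pct > 100 + 1e-9)) {
    stop("movement time exceeds capture duration")
  }
  structure(
    list(
      device_id = trace$device_id,
      capture_time_s = capture_time_s,
      capture_depth_m = capture_depth_m,
      haul_time_s = haul_time_s,
      capture_duration_min = duration_min,
      movement = movement
    ),
    class = "capture_summary"
  )
}

#' @export
print.capture_summary <- function(x, ...) {
  cat(sprintf("Capture summary for %s\n", x$device_id))
  cat(sprintf("  capture at %.0f s (baseline depth %.2f m), hauled at %.0f s\n",
              x$capture_time_s, x$capture_depth_m, x$haul_time_s))
  cat(sprintf("  capture duration: %.1f min\n", x$capture_duration_min))
  for (i in seq_len(nrow(x$movement))) {
    m <- x$movement[i, ]
    cat(sprintf("  %3.0f%% threshold: %d bout(s), %.1f min moving (%.1f%% of capture)\n",
                100 * m$threshold_fraction, m$n_bouts, m$movement_min,
                m$movement_pct))
  }
  invisible(x)
}

#' @export
as.data.frame.capture_summary <- function(x, ...) {
  row <- data.frame(
    device_id = x$device_id,
    capture_time_s = x$capture_time_s,
    capture_depth_m = x$capture_depth_m,
    haul_time_s = x$haul_time_s,
    capture_duration_min = x$capture_duration_min
  )
  for (i in seq_len(nrow(x$movement))) {
    m <- x$movement[i, ]
    tag <- sprintf("%.0f", 100 * m$threshold_fraction)
    row[[paste0("movement_min_", tag)]] <- m$movement_min
    row[[paste0("movement_pct_", tag)]] <- m$movement_pct
  }
  row
}

#' Run the full behavioural pipeline on one trace
#'
#' Detects the capture point, finds (or accepts) the haul point, builds the
#' baseline schedule, computes the deviation series and detects movement
#' bouts at every configured threshold fraction.
#'
#' @param trace A [depth_trace()].
#' @param gear A [gear_config()].
#' @param haul_time_s Haul time (s); auto-detected with [detect_haul_point()]
#'   when NULL.
#' @param refine Passed to [build_baseline_schedule()].
#' @return A list of class `capture_analysis` with elements `capture`,
#'   `summary` (NULL when no capture was detected), `schedule`, `deviations`
#'   and `bouts` (named list by threshold fraction).
#' @export
analyze_trace <- function(trace, gear = gear_config(), haul_time_s = NULL,
                          refine = TRUE) {
  cp <- detect_capture_point(trace, gear)
  if (!cp$detected) {
    return(structure(
      list(capture = cp, summary = NULL, schedule = NULL,
           deviations = NULL, bouts = NULL),
      class = "capture_analysis"
    ))
  }
  if (is.null(haul_time_s)) {
    haul_time_s <- detect_haul_point(trace, cp$capture_time_s)
  }
  schedule <- build_baseline_schedule(trace, cp$capture_time_s, haul_time_s,
                                      gear, refine = refine)
  dev <- deviation_series(trace, schedule)
  bouts <- lapply(gear$threshold_fractions, function(f) detect_bouts(dev, f, gear))
  names(bouts) <- as.character(gear$threshold_fractions)
  summary <- summarize_capture(trace, cp$capture_time_s, haul_time_s, bouts,
                               capture_depth_m = cp$capture_depth_m)
  structure(
    list(capture = cp, summary = summary, schedule = schedule,
         deviations = dev, bouts = bouts),
    class = "capture_analysis"
  )
}
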