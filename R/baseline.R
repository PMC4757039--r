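# Baseline scheduling and deviation machinery for the five-step
# depth-trace algorithm:
#   1. steady-state baseline (1-min mean) before the capture point,
#      recalculated every 30 min and across significant tidal shifts;
#   2. per-sample absolute deviation from the covering baseline;
#   3. movement thresholds = fraction x effective extension + baseline s.d.;
#   4. supra-threshold runs with <= 4 s gaps bridged are movement bouts;
#   5. samples beyond the haul point are excluded.

# mean/sd of depths with time in [end_s - window, end_s)
.window_stats <- function(trace, end_s, window_s) {
  sel <- trace$times >= (end_s - window_s) & trace$times < end_s
  if (sum(sel) < 2L) {
    stop(sprintf("baseline window ending at %.1f s has < 2 samples", end_s))
  }
  d <- trace$depths[sel]
  list(mean = mean(d), sd = stats::sd(d), n = sum(sel), depths = d)
}

.make_schedule_df <- function(starts, ends, means, sds, source) {
  structure(
    data.frame(
      start_s = starts, end_s = ends,
      baseline_depth_m = means, baseline_sd_m = sds,
      source = source, stringsAsFactors = FALSE
    ),
    class = c("baseline_schedule", "data.frame")
  )
}

.validate_schedule <- function(schedule, capture_time_s, haul_time_s) {
  if (nrow(schedule) == 0L) stop("empty baseline schedule")
  ok <- abs(schedule$start_s[1L] - capture_time_s) < 1e-9 &&
    abs(schedule$end_s[nrow(schedule)] - haul_time_s) < 1e-9 &&
    all(schedule$end_s > schedule$start_s) &&
    (nrow(schedule) == 1L ||
       all(abs(schedule$start_s[-1L] - schedule$end_s[-nrow(schedule)]) < 1e-9))
  if (!ok) stop("baseline schedule does not tile [capture, haul] without gaps/overlaps")
  if (any(schedule$baseline_sd_m < 0)) stop("negative baseline s.d.")
  invisible(schedule)
}

#' Build the baseline schedule for a capture
#'
#' Computes the steady-state baseline depth (1-min mean) and its standard
#' deviation immediately before the capture point, then recalculates it at the
#' end of every 30-min block (tracking tidal depth change) and, optionally,
#' across movement bouts that straddle a significant tidal shift. A shift is
#' deemed significant when the 1-min mean depths before and after a bout
#' differ by more than `tidal_shift_sigma` baseline standard deviations; the
#' recalculated baseline is then the average of the two flanking 1-min
#' windows. The resulting segments tile `[capture_time_s, haul_time_s)`; a
#' sample exactly on a boundary belongs to the later segment.
#'
#' @param trace A [depth_trace()].
#' @param capture_time_s,haul_time_s Capture and haul times (s from trace
#'   start); the capture must be preceded by at least one full baseline
#'   window.
#' @param gear A [gear_config()].
#' @param refine Run the steady-state refinement pass (default TRUE): bouts
#'   are detected against a provisional schedule at the lowest threshold
#'   fraction, 30-min recalculation windows that land inside a movement bout
#'   are slid back to the nearest quiescent 1-min window (a baseline must be
#'   a *steady-state* depth), and segments are split across bouts whose
#'   flanking means shift significantly (tidal recalculation).
#' @return A `baseline_schedule` data frame with columns `start_s`, `end_s`,
#'   `baseline_depth_m`, `baseline_sd_m`, `source`.
#' @export
build_baseline_schedule <- function(trace, capture_time_s, haul_time_s,
                                    gear = gear_config(), refine = TRUE) {
  stopifnot(inherits(trace, "depth_trace"))
  if (haul_time_s <= capture_time_s) stop("haul_time_s must exceed capture_time_s")
  if (capture_time_s - trace$times[1L] < gear$baseline_window_s) {
    stop("capture point is not preceded by a full baseline window")
  }
  starts <- seq(capture_time_s, haul_time_s, by = gear$baseline_recalc_interval_s)
  starts <- starts[starts < haul_time_s]
  ends <- c(starts[-1L], haul_time_s)
  stats_list <- lapply(starts, function(s) .window_stats(trace, s, gear$baseline_window_s))
  schedule <- .make_schedule_df(
    starts, ends,
    vapply(stats_list, `[[`, numeric(1L), "mean"),
    vapply(stats_list, `[[`, numeric(1L), "sd"),
    c("pre-capture", rep("recalc-30min", length(starts) - 1L))
  )
  .validate_schedule(schedule, capture_time_s, haul_time_s)

  if (!refine) return(schedule)

  w <- gear$baseline_window_s
  dev <- deviation_series(trace, schedule)
  bouts <- detect_bouts(dev, min(gear$threshold_fractions), gear)
  if (nrow(bouts) == 0L) return(schedule)

  # steady-state pass: a 30-min recalculation window overlapping a movement
  # bout (padded, to clear the bout's sub-threshold shoulders) or showing an
  # inflated s.d. is slid back to the nearest quiescent 1-min window; the
  # pre-capture window is pre-movement by construction and never moved
  pad <- 2 * gear$cessation_gap_s + 12
  sd_ref <- max(schedule$baseline_sd_m[1L], 0.01)
  window_busy <- function(end_s, exclude = 0L) {
    lo <- bouts$start_s - pad
    hi <- bouts$end_s + pad
    if (exclude > 0L) {
      lo <- lo[-exclude]
      hi <- hi[-exclude]
    }
    any(lo < end_s & hi > end_s - w)
  }
  # a candidate window must also agree with the robust (median) depth of the
  # trailing half-hour: a window sitting on an undetected excursion plateau
  # has a steady s.d. but a mean shifted by the full bout amplitude
  med_tol <- 0.25 * min(gear$threshold_fractions) * gear$effective_extension_m + 3 * sd_ref
  steady_window <- function(boundary_s, floor_s) {
    # the median anchor never reaches across a segment boundary, so a real
    # tidal split upstream does not poison it
    sel <- trace$times >= max(boundary_s - gear$baseline_recalc_interval_s,
                              floor_s - w) &
      trace$times < boundary_s
    med <- stats::median(trace$depths[sel])
    end_s <- boundary_s
    best <- NULL
    best_score <- Inf
    while (end_s >= floor_s) {
      st <- .window_stats(trace, end_s, w)
      ok <- !window_busy(end_s) && st$sd <= 2 * sd_ref &&
        abs(st$mean - med) <= med_tol
      if (ok) return(st)
      score <- abs(st$mean - med) + st$sd
      if (score < best_score) {
        best <- st
        best_score <- score
      }
      end_s <- end_s - trace$sample_interval_s
    }
    best # least-disturbed window when nothing fully quiescent exists
  }
  # --- tidal pass: recalculate across movement periods that straddle a
  # significant tidal depth change ---
  dt <- trace$sample_interval_s
  for (i in seq_len(nrow(bouts))) {
    b_start <- bouts$start_s[i]
    b_end <- bouts$end_s[i]
    if (b_start - w < trace$times[1L] || b_end + w > haul_time_s) next
    # stabilised-tail rule: after a real tidal shift the depth settles at a
    # new level while still reading as supra-threshold deviation, so the
    # detected bout runs long; movement has actually ceased once the tail is
    # steady AND that level persists beyond the detected bout end
    b_end_eff <- b_end
    sel <- which(trace$times >= b_start & trace$times < b_end)
    if (length(sel) >= 2L) {
      d <- trace$depths[sel]
      n_s <- length(d)
      suf_n <- n_s - seq_len(n_s) + 1
      suf_mean <- rev(cumsum(rev(d))) / suf_n
      suf_var <- pmax(0, (rev(cumsum(rev(d^2))) - suf_n * suf_mean^2) /
                        pmax(suf_n - 1, 1))
      steady <- sqrt(suf_var) <= 2 * sd_ref & suf_n * dt >= w
      j <- which(steady)[1L]
      if (!is.na(j) && j > 1L) {
        probe <- trace$times >= b_end & trace$times < b_end + w
        if (sum(probe) >= 2L &&
            abs(mean(trace$depths[probe]) - suf_mean[j]) <= 3 * sd_ref) {
          b_end_eff <- trace$times[sel[j]]
        }
      }
    }
    # flanking windows must be clear of every other detected bout and steady
    if (window_busy(b_start, exclude = i) ||
        window_busy(b_end_eff + w, exclude = i)) {
      next
    }
    pre <- .window_stats(trace, b_start, w)
    post_sel <- trace$times >= b_end_eff & trace$times < b_end_eff + w
    if (sum(post_sel) < 2L) next
    post_d <- trace$depths[post_sel]
    if (pre$sd > 2 * sd_ref || stats::sd(post_d) > 2 * sd_ref) next
    seg_idx <- findInterval(b_start, schedule$start_s)
    seg_sd <- schedule$baseline_sd_m[seg_idx]
    shift <- abs(mean(post_d) - pre$mean)
    if (shift <= gear$tidal_shift_sigma * seg_sd) next
    # split the covering segment at the end of the movement period; the new
    # baseline averages the 1-min windows flanking the movement period
    new_mean <- mean(c(pre$depths, post_d))
    new_sd <- sqrt((stats::var(pre$depths) + stats::var(post_d)) / 2)
    k <- findInterval(b_end_eff, schedule$start_s)
    if (b_end_eff <= schedule$start_s[k] || b_end_eff >= schedule$end_s[k]) next
    top <- schedule[seq_len(k), , drop = FALSE]
    top$end_s[k] <- b_end_eff
    bottom <- schedule[seq(k, nrow(schedule)), , drop = FALSE]
    bottom$start_s[1L] <- b_end_eff
    bottom$baseline_depth_m[1L] <- new_mean
    bottom$baseline_sd_m[1L] <- new_sd
    bottom$source[1L] <- "tidal-recalc"
    schedule <- .make_schedule_df(
      c(top$start_s, bottom$start_s), c(top$end_s, bottom$end_s),
      c(top$baseline_depth_m, bottom$baseline_depth_m),
      c(top$baseline_sd_m, bottom$baseline_sd_m),
      c(top$source, bottom$source)
    )
  }
  dev <- deviation_series(trace, schedule)
  bouts <- detect_bouts(dev, min(gear$threshold_fractions), gear)
  if (nrow(bouts) == 0L) {
    return(.validate_schedule(schedule, capture_time_s, haul_time_s))
  }

  # --- steady-state pass for the 30-min recalculation windows ---
  if (nrow(schedule) > 1L) {
    for (pass in 1:2) {
      for (k in seq.int(2L, nrow(schedule))) {
        if (schedule$source[k] == "tidal-recalc") next
        floor_s <- max(schedule$start_s[k - 1L] + w, trace$times[1L] + w)
        st <- steady_window(schedule$start_s[k], floor_s)
        schedule$baseline_depth_m[k] <- st$mean
        schedule$baseline_sd_m[k] <- st$sd
      }
      # re-detect bouts against the cleaned schedule
      dev <- deviation_series(trace, schedule)
      bouts <- detect_bouts(dev, min(gear$threshold_fractions), gear)
      if (nrow(bouts) == 0L) break
    }
  }
  .validate_schedule(schedule, capture_time_s, haul_time_s)
}

#' Per-sample absolute deviation from the baseline schedule
#'
#' Step 2 of the algorithm: for every sample inside the capture window the
#' absolute difference between recorded depth and the covering segment's
#' baseline depth. Samples at or beyond the haul point (and before the capture
#' point) are excluded.
#'
#' @param trace A [depth_trace()].
#' @param schedule A `baseline_schedule` from [build_baseline_schedule()].
#' @return Data frame with columns `time_s`, `depth_m`, `segment`,
#'   `baseline_depth_m`, `baseline_sd_m`, `deviation_m`, plus the sampling
#'   step as attribute `sample_interval_s`.
#' @export
deviation_series <- function(trace, schedule) {
  stopifnot(inherits(trace, "depth_trace"), inherits(schedule, "data.frame"))
  t0 <- schedule$start_s[1L]
  t1 <- schedule$end_s[nrow(schedule)]
  sel <- trace$times >= t0 & trace$times < t1
  tms <- trace$times[sel]
  seg <- findInterval(tms, schedule$start_s)
  if (any(seg < 1L) || any(tms >= schedule$end_s[seg])) {
    stop("sample not covered by exactly one baseline segment")
  }
  out <- data.frame(
    time_s = tms,
    depth_m = trace$depths[sel],
    segment = seg,
    baseline_depth_m = schedule$baseline_depth_m[seg],
    baseline_sd_m = schedule$baseline_sd_m[seg]
  )
  out$deviation_m <- abs(out$depth_m - out$baseline_depth_m)
  attr(out, "sample_interval_s") <- trace$sample_interval_s
  out
}

#' Movement threshold for a baseline segment
#'
#' Step 3: the threshold at a given fraction of the effective gangion
#' extension, inflated by the segment's baseline standard deviation to absorb
#' surface swell. With the default gear, fraction 1 gives 0.60 m + s.d. and
#' fraction 0.5 gives 0.30 m + s.d.
#'
#' @param segment One or more rows of a `baseline_schedule` (uses
#'   `baseline_sd_m`).
#' @param fraction Threshold fraction; must be one of
#'   `gear$threshold_fractions`.
#' @param gear A [gear_config()].
#' @return Threshold(s) in metres, one per segment row.
#' @examples
#' sched <- data.frame(baseline_sd_m = c(0, 0.04))
#' movement_threshold(sched, 1, gear_config())   # 0.60, 0.64
#' movement_threshold(sched, 0.5, gear_config()) # 0.30, 0.34
#' @export
movement_threshold <- function(segment, fraction, gear = gear_config()) {
  if (!any(abs(gear$threshold_fractions - fraction) < 1e-12)) {
    stop(sprintf("fraction %g is not one of gear$threshold_fractions", fraction))
  }
  sd_m <- segment$baseline_sd_m
  if (any(sd_m < 0)) stop("baseline_sd_m must be >= 0")
  fraction * gear$effective_extension_m + sd_m
}
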