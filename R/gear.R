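#' Longline gear and detection configuration
#'
#' Bundles the physical gear geometry and the detection parameters used by the
#' depth-trace pipeline. The effective gangion extension -- the maximum
#' vertical deviation the device can register from the mainline -- is the
#' gangion length minus the device's mounting offset from the hook eye
#' (0.70 m - 0.10 m = 0.60 m with the defaults).
#'
#' @param gangion_length_m Length of the branch line connecting hook to
#'   mainline (m). Default 0.70.
#' @param tdr_offset_m Distance of the depth recorder from the hook eye (m).
#'   Default 0.10.
#' @param threshold_fractions Fractions of the effective extension at which
#'   movement is scored. Default `c(0.5, 1)`: "intermediate" movement at half
#'   extension and escape attempts at full extension.
#' @param baseline_window_s Length of the steady-state window used to estimate
#'   a baseline depth and its s.d. (s). Default 60.
#' @param baseline_recalc_interval_s Interval at which the baseline is
#'   recalculated to track tidal depth change (s). Default 1800 (30 min).
#' @param cessation_gap_s Movement is deemed to have ceased only when the
#'   threshold is unmet for more than this many seconds; shorter sub-threshold
#'   gaps are bridged and counted as movement. Default 4.
#' @param capture_min_run_samples Number of consecutive supra-threshold samples
#'   required to confirm the capture point (guards against single-sample swell
#'   spikes). Default 3 (6 s at a 2-s sampling interval).
#' @param tidal_shift_sigma A movement bout triggers a mid-schedule baseline
#'   recalculation when the depth shift across it exceeds this many baseline
#'   standard deviations. Default 3.
#'
#' @return An object of class `gear_config` (a named list) with the additional
#'   computed field `effective_extension_m`.
#' @examples
#' gear <- gear_config()
#' gear$effective_extension_m # 0.6
#' @export
gear_config <- function(gangion_length_m = 0.70,
                        tdr_offset_m = 0.10,
                        threshold_fractions = c(0.5, 1),
                        baseline_window_s = 60,
                        baseline_recalc_interval_s = 1800,
                        cessation_gap_s = 4,
                        capture_min_run_samples = 3,
                        tidal_shift_sigma = 3) {
  stopifnot(
    is.numeric(gangion_length_m), length(gangion_length_m) == 1L,
    is.numeric(tdr_offset_m), length(tdr_offset_m) == 1L
  )
  if (!(tdr_offset_m > 0 && tdr_offset_m < gangion_length_m)) {
    stop("tdr_offset_m must lie strictly between 0 and gangion_length_m")
  }
  if (!all(threshold_fractions > 0 & threshold_fractions <= 1)) {
    stop("threshold_fractions must lie in (0, 1]")
  }
  if (baseline_window_s <= 0 || baseline_recalc_interval_s <= 0) {
    stop("baseline windows must be positive")
  }
  if (cessation_gap_s < 0) stop("cessation_gap_s must be >= 0")
  if (capture_min_run_samples < 1) stop("capture_min_run_samples must be >= 1")
  structure(
    list(
      gangion_length_m = gangion_length_m,
      tdr_offset_m = tdr_offset_m,
      effective_extension_m = gangion_length_m - tdr_offset_m,
      threshold_fractions = sort(threshold_fractions),
      baseline_window_s = baseline_window_s,
      baseline_recalc_interval_s = baseline_recalc_interval_s,
      cessation_gap_s = cessation_gap_s,
      capture_min_run_samples = capture_min_run_samples,
      tidal_shift_sigma = tidal_shift_sigma
    ),
    class = "gear_config"
  )
}

#' @export
print.gear_config <- function(x, ...) {
  cat("Longline gear configuration\n")
  cat(sprintf("  gangion length        : %.2f m\n", x$gangion_length_m))
  cat(sprintf("  TDR offset from hook  : %.2f m\n", x$tdr_offset_m))
  cat(sprintf("  effective extension   : %.2f m\n", x$effective_extension_m))
  cat(sprintf("  threshold fractions   : %s\n",
              paste(x$threshold_fractions, collapse = ", ")))
  cat(sprintf("  baseline window       : %d s, recalculated every %d s\n",
              as.integer(x$baseline_window_s),
              as.integer(x$baseline_recalc_interval_s)))
  cat(sprintf("  movement cessation gap: %g s\n", x$cessation_gap_s))
  invisible(x)
}
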