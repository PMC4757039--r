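#' Depth trace container
#'
#' A uniformly sampled depth time series for a single hook/animal. Depth is in
#' metres, positive downward; time is seconds since the start of the trace,
#' with a constant sampling step (2 s for the LAT1100-style deployment the
#' defaults describe).
#'
#' @param times Numeric vector of sample times (s since trace start), strictly
#'   increasing on a uniform grid.
#' @param depths Numeric vector of depths (m, positive down), finite and >= 0.
#' @param device_id Identifier of the recording device.
#' @param sample_interval_s Sampling step (s); must match the time grid.
#'
#' @return Object of class `depth_trace`: a list with fields `times`,
#'   `depths`, `device_id`, `sample_interval_s`.
#' @export
depth_trace <- function(times, depths, device_id = "TDR",
                        sample_interval_s = NULL) {
  times <- as.numeric(times)
  depths <- as.numeric(depths)
  if (length(times) != length(depths)) {
    stop("times and depths must have equal length")
  }
  if (length(times) < 2L) stop("a depth trace needs at least 2 samples")
  steps <- diff(times)
  if (any(steps <= 0)) {
    i <- which(steps <= 0)[1L]
    stop(sprintf("times must be strictly increasing; violation at row %d", i + 1L))
  }
  if (is.null(sample_interval_s)) sample_interval_s <- stats::median(steps)
  if (any(abs(steps - sample_interval_s) > 1e-6 * sample_interval_s)) {
    i <- which(abs(steps - sample_interval_s) > 1e-6 * sample_interval_s)[1L]
    stop(sprintf(
      "non-uniform sampling: step %.6g s at row %d (expected %.6g s)",
      steps[i], i + 1L, sample_interval_s
    ))
  }
  if (anyNA(depths) || any(!is.finite(depths))) {
    i <- which(!is.finite(depths))[1L]
    stop(sprintf("depths must be finite; offending row %d", i))
  }
  if (any(depths < 0)) {
    i <- which(depths < 0)[1L]
    stop(sprintf("depths must be >= 0 (positive downward); offending row %d", i))
  }
  structure(
    list(
      times = times, depths = depths,
      device_id = as.character(device_id),
      sample_interval_s = sample_interval_s
    ),
    class = "depth_trace"
  )
}

#' @export
print.depth_trace <- function(x, ...) {
  cat(sprintf(
    "<depth_trace %s: %d samples @ %gs, %.1f-%.1f m, %.1f min>\n",
    x$device_id, length(x$times), x$sample_interval_s,
    min(x$depths), max(x$depths), diff(range(x$times)) / 60
  ))
  invisible(x)
}

#' @export
length.depth_trace <- function(x) length(x$times)

#' Read a depth trace from delimited text
#'
#' Expects a header row with columns `time` and `depth` (a `temperature`
#' column, if present, is carried along but unused). `time` may be numeric
#' seconds or ISO-8601 timestamps; timestamps are converted to seconds from
#' the first sample. Depth is metres, positive downward.
#'
#' Rows with missing depth are tolerated up to 1% of the trace and filled by
#' linear interpolation (with a warning); more than that is a hard error
#' naming the first offending row. Duplicated or decreasing timestamps and
#' non-uniform sampling are hard errors unless `resample` is set, in which
#' case the series is linearly resampled onto a uniform grid at the median
#' step.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @param device_id Device identifier; defaults to the file name.
#' @param resample Resample non-uniform input onto a uniform grid instead of
#'   rejecting it. Default FALSE.
#' @return A [depth_trace()].
#' @export
read_trace <- function(path, sep = ",", device_id = NULL, resample = FALSE) {
  if (is.null(device_id)) {
    device_id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(c("time", "depth"), names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  tm <- df$time
  if (is.character(tm) || inherits(tm, "factor")) {
    parsed <- suppressWarnings(as.numeric(tm))
    if (anyNA(parsed)) {
      ts <- as.POSIXct(tm, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS"))
      if (anyNA(ts)) {
        stop(sprintf("unparsable time value at row %d", which(is.na(ts))[1L]))
      }
      tm <- as.numeric(ts) - as.numeric(ts[1L])
    } else {
      tm <- parsed
    }
  }
  tm <- tm - tm[1L]
  if (any(diff(tm) == 0)) {
    stop(sprintf("duplicated timestamp at row %d", which(diff(tm) == 0)[1L] + 1L))
  }
  if (any(diff(tm) < 0)) {
    stop(sprintf("non-monotone time at row %d", which(diff(tm) < 0)[1L] + 1L))
  }
  depth <- as.numeric(df$depth)
  n_na <- sum(is.na(depth))
  if (n_na > 0) {
    if (n_na > 0.01 * length(depth)) {
      stop(sprintf("more than 1%% of depth samples missing; first at row %d",
                   which(is.na(depth))[1L]))
    }
    warning(sprintf("%d missing depth sample(s) linearly interpolated", n_na))
    depth <- stats::approx(tm[!is.na(depth)], depth[!is.na(depth)],
                           xout = tm, rule = 2)$y
  }
  steps <- diff(tm)
  step <- stats::median(steps)
  uniform <- all(abs(steps - step) <= 1e-6 * step)
  if (!uniform) {
    if (!resample) {
      i <- which(abs(steps - step) > 1e-6 * step)[1L]
      stop(sprintf(
        "non-uniform sampling at row %d (step %.6g s, expected %.6g s); set resample = TRUE to regrid",
        i + 1L, steps[i], step
      ))
    }
    grid <- seq(tm[1L], tm[length(tm)], by = step)
    depth <- stats::approx(tm, depth, xout = grid, rule = 2)$y
    tm <- grid
  }
  depth_trace(tm, depth, device_id = device_id, sample_interval_s = step)
}

#' Write a depth trace as delimited text
#'
#' Emits the dialect [read_trace()] consumes: a header `time,depth` and one
#' row per sample (time in seconds from trace start).
#'
#' @param trace A [depth_trace()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sep = ",") {
  stopifnot(inherits(trace, "depth_trace"))
  # %.17g so that doubles survive the round trip bit-for-bit
  df <- data.frame(time = sprintf("%.17g", trace$times),
                   depth = sprintf("%.17g", trace$depths))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
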