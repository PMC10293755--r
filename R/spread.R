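# Thermal-spread measurement: threshold segmentation of a thermogram
# sequence and conversion of the segmented pixel count to mm^2.
#
# The headline quantity is the CUMULATIVE spread: a pixel counts as damaged
# if it EVER exceeds the threshold anywhere in the recording (strict ">").
# The per-frame area series is reported alongside so the per-frame reading
# remains recoverable.

#' Segment one frame at a temperature threshold
#'
#' @param frame A [thermogram_frame()] or bare numeric matrix of degC.
#' @param threshold_c Threshold in degC. Pixels strictly greater than the
#'   threshold are marked; a pixel exactly at the threshold is not.
#' @return Object of class `binary_mask`: logical matrix `values` plus
#'   `threshold_c`.
#' @export
threshold_mask <- function(frame, threshold_c = 60) {
  m <- if (inherits(frame, "thermogram_frame")) frame$values else frame
  if (!is.matrix(m) || !is.numeric(m)) stop_value("frame must be a numeric matrix")
  if (anyNA(m) || any(!is.finite(m))) stop_value("frame contains non-finite temperatures")
  if (!is_scalar_number(threshold_c)) stop_value("threshold_c must be a single number")
  structure(list(values = m > threshold_c, threshold_c = threshold_c),
            class = "binary_mask")
}

#' Cumulative exceedance mask over a whole sequence
#'
#' Union over frames of [threshold_mask()]: marked where the temperature
#' ever exceeds the threshold during the recording.
#'
#' @inheritParams threshold_mask
#' @param seq A [thermogram_sequence()].
#' @param min_frames_above Debounce: a pixel must exceed the threshold in at
#'   least this many frames (default 1 = plain union). A noise-limited
#'   sensor (NETD ~0.1 degC) can flicker single pixels across the threshold;
#'   raising this gates such flicker out.
#' @return A `binary_mask`.
#' @export
cumulative_mask <- function(seq, threshold_c = 60, min_frames_above = 1L) {
  stopifnot(inherits(seq, "thermogram_sequence"))
  if (min_frames_above < 1L) stop_value("min_frames_above must be >= 1")
  counts <- Reduce(`+`, lapply(seq$frames, function(f) {
    threshold_mask(f, threshold_c)$values
  }))
  structure(list(values = counts >= min_frames_above, threshold_c = threshold_c),
            class = "binary_mask")
}

#' Measure thermal spread from a thermogram sequence
#'
#' The whole measurement in one call: cumulative exceedance area (mm^2),
#' the per-frame area series, and the peak temperature over the recording.
#'
#' @inheritParams cumulative_mask
#' @param cal A `pixel_calibration` (see [compute_pixel_size()]).
#' @return Object of class `spread_result` with `cumulative_area_mm2`,
#'   `per_frame` (data.frame: `timestamp_s`, `area_mm2`),
#'   `peak_temperature_c`, `threshold_c`, `calibration` and the cumulative
#'   `mask`.
#' @export
#' @examples
#' seq <- thermogram_sequence(list(matrix(37, 4, 4), matrix(c(70, rep(37, 15)), 4, 4)),
#'                            frame_rate_hz = 10)
#' analyze_spread(seq, 60, pixel_calibration(1))$cumulative_area_mm2 # 1
analyze_spread <- function(seq, threshold_c = 60, cal, min_frames_above = 1L) {
  stopifnot(inherits(seq, "thermogram_sequence"), inherits(cal, "pixel_calibration"))
  mask <- cumulative_mask(seq, threshold_c, min_frames_above)
  per_frame <- data.frame(
    timestamp_s = sequence_timestamps(seq),
    area_mm2 = vapply(seq$frames, function(f) {
      scaled_area(sum(threshold_mask(f, threshold_c)$values), cal)
    }, numeric(1))
  )
  structure(list(
    cumulative_area_mm2 = scaled_area(sum(mask$values), cal),
    per_frame = per_frame,
    peak_temperature_c = max(vapply(seq$frames, function(f) max(f$values), numeric(1))),
    threshold_c = threshold_c,
    calibration = cal,
    mask = mask
  ), class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("<spread_result> cumulative %.2f mm^2 above %.1f degC; peak %.1f degC over %d frame(s)\n",
              x$cumulative_area_mm2, x$threshold_c, x$peak_temperature_c, nrow(x$per_frame)))
  invisible(x)
}

#' Area of the largest 4-connected component of a mask
#'
#' Optional robustness filter (off by default in the pipeline): keeps only
#' the dominant contiguous lesion, discarding isolated noise pixels.
#'
#' @param mask A `binary_mask`.
#' @param cal A `pixel_calibration`.
#' @return Area in mm^2 of the largest 4-connected TRUE component (0 for an
#'   empty mask).
#' @export
largest_component_area <- function(mask, cal) {
  stopifnot(inherits(mask, "binary_mask"), inherits(cal, "pixel_calibration"))
  m <- mask$values
  if (!any(m)) return(0)
  labels <- label_components(m)
  scaled_area(max(tabulate(labels[labels > 0L])), cal)
}

# 4-connected component labelling by iterative label propagation.
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  lab[m] <- seq_len(sum(m))
  repeat {
    nxt <- lab
    # propagate the minimum positive neighbour label in the 4-neighbourhood
    up    <- rbind(lab[1, , drop = FALSE] * 0L, lab[-nr, , drop = FALSE])
    down  <- rbind(lab[-1, , drop = FALSE], lab[nr, , drop = FALSE] * 0L)
    left  <- cbind(lab[, 1, drop = FALSE] * 0L, lab[, -nc, drop = FALSE])
    right <- cbind(lab[, -1, drop = FALSE], lab[, nc, drop = FALSE] * 0L)
    for (nb in list(up, down, left, right)) {
      take <- m & nb > 0L & (nxt == 0L | nb < nxt)
      nxt[take] <- nb[take]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}
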