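# Thermogram containers.
#
# Pixel values are ALWAYS temperatures in degrees Celsius -- never raw sensor
# counts, never Kelvin. Values outside [-40, 400] are rejected as probable
# unit errors for this application. Image convention: row 1 of the matrix is
# the top of the image; fiducial coordinates are 0-based pixel-center
# (row, col) pairs.

TEMP_MIN_C <- -40
TEMP_MAX_C <- 400

#' Construct a single thermogram frame
#'
#' A frame is a 2-D grid of temperatures (degrees C) plus a timestamp in
#' seconds from the start of its sequence.
#'
#' @param values Numeric matrix of temperatures in degrees C. All values must
#'   be finite and within \[-40, 400\] (physically plausible range for
#'   electrosurgery monitoring; anything else is treated as a unit error).
#' @param timestamp Seconds from sequence start (single non-negative number).
#' @return An object of class `thermogram_frame` with elements `values` and
#'   `timestamp`.
#' @export
#' @examples
#' f <- thermogram_frame(matrix(37, 4, 5), timestamp = 0)
thermogram_frame <- function(values, timestamp = 0) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_value("frame values must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_value("frame contains non-finite temperatures")
  }
  if (any(values < TEMP_MIN_C) || any(values > TEMP_MAX_C)) {
    stop_value(sprintf(
      "frame temperatures outside [%g, %g] degC; probable unit error (values must be degC)",
      TEMP_MIN_C, TEMP_MAX_C))
  }
  if (!is_scalar_number(timestamp) || timestamp < 0) {
    stop_value("timestamp must be a single non-negative number (seconds)")
  }
  structure(list(values = values, timestamp = as.numeric(timestamp)),
            class = "thermogram_frame")
}

#' Construct a thermogram sequence
#'
#' Ordered temperature frames with an acquisition frame rate and free-form
#' metadata (ambient temperature, chamber pressure, source tag).
#'
#' @param frames List of [thermogram_frame()] objects (or bare numeric
#'   matrices, which get timestamps `index/frame_rate`). At least one frame;
#'   all frames must share one grid size; timestamps strictly increasing.
#' @param frame_rate_hz Acquisition rate in Hz. Required when frames carry no
#'   timestamps. When both are present, timestamps must agree with
#'   `index/frame_rate_hz` within 1 ms.
#' @param meta Named list; recognised keys `ambient_c`, `pressure_mmhg`,
#'   `source`.
#' @return An object of class `thermogram_sequence`.
#' @export
#' @examples
#' seq <- thermogram_sequence(list(matrix(37, 2, 2), matrix(38, 2, 2)),
#'                            frame_rate_hz = 10)
#' seq$frames[[2]]$timestamp # 0.1
thermogram_sequence <- function(frames, frame_rate_hz = NULL, meta = list()) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_value("a thermogram sequence needs at least 1 frame")
  }
  bare <- vapply(frames, is.matrix, logical(1))
  if (any(bare) && is.null(frame_rate_hz)) {
    stop_value("frame_rate_hz is required to synthesize timestamps for bare matrices")
  }
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (is.matrix(f)) f <- thermogram_frame(f, timestamp = (i - 1L) / frame_rate_hz)
    if (!inherits(f, "thermogram_frame")) {
      stop_value("frames must be thermogram_frame objects or numeric matrices")
    }
    f
  })
  dims <- vapply(frames, function(f) dim(f$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_value("grid dimensions must be constant within a sequence")
  }
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    stop_value("timestamps must be strictly increasing")
  }
  if (!is.null(frame_rate_hz)) {
    if (!is_scalar_number(frame_rate_hz) || frame_rate_hz <= 0) {
      stop_value("frame_rate_hz must be a positive number")
    }
    expected <- (seq_along(frames) - 1L) / frame_rate_hz
    if (max(abs(ts - expected)) > 1e-3) {
      stop_value("timestamps disagree with index/frame_rate_hz by more than 1 ms")
    }
  }
  structure(list(frames = frames,
                 frame_rate_hz = if (is.null(frame_rate_hz)) NA_real_ else as.numeric(frame_rate_hz),
                 meta = meta),
            class = "thermogram_sequence")
}

#' @export
length.thermogram_sequence <- function(x) length(x$frames)

#' @export
print.thermogram_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$values)
  cat(sprintf("<thermogram_sequence> %d frame(s) of %d x %d px", length(x$frames), d[1], d[2]))
  if (!is.na(x$frame_rate_hz)) cat(sprintf(" @ %g Hz", x$frame_rate_hz))
  rng <- range(vapply(x$frames, function(f) range(f$values), numeric(2)))
  cat(sprintf(", range %.2f..%.2f degC\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
print.thermogram_frame <- function(x, ...) {
  cat(sprintf("<thermogram_frame> %d x %d px at t=%.3f s, range %.2f..%.2f degC\n",
              nrow(x$values), ncol(x$values), x$timestamp,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Per-frame temperature summary
#'
#' Quick QC table: one row per frame with min, mean and max temperature.
#'
#' @param seq A [thermogram_sequence()].
#' @return A data.frame with columns `frame`, `timestamp_s`, `min_c`,
#'   `mean_c`, `max_c`.
#' @export
frame_stats <- function(seq) {
  stopifnot(inherits(seq, "thermogram_sequence"))
  data.frame(
    frame = seq_along(seq$frames),
    timestamp_s = vapply(seq$frames, function(f) f$timestamp, numeric(1)),
    min_c = vapply(seq$frames, function(f) min(f$values), numeric(1)),
    mean_c = vapply(seq$frames, function(f) mean(f$values), numeric(1)),
    max_c = vapply(seq$frames, function(f) max(f$values), numeric(1))
  )
}

# stack frames into rows x cols x nframes array (internal)
sequence_array <- function(seq) {
  d <- dim(seq$frames[[1]]$values)
  arr <- array(NA_real_, c(d[1], d[2], length(seq$frames)))
  for (i in seq_along(seq$frames)) arr[, , i] <- seq$frames[[i]]$values
  arr
}

sequence_timestamps <- function(seq) {
  vapply(seq$frames, function(f) f$timestamp, numeric(1))
}
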