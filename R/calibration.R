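# Pixel-size calibration from an in-scene fiducial of known length
# (in the physical experiment, the scalpel tip). Pixels are assumed square
# and uniform, so a single scalar scale converts pixel counts to mm^2.

#' Calibrate pixel size from a fiducial of known length
#'
#' Two pixel endpoints of an in-scene object of known physical length give
#' the image scale: `mm_per_pixel = known_length_mm / |p1 - p2|` (Euclidean
#' pixel distance). Coordinates are 0-based pixel-center `(row, col)` pairs;
#' only their difference matters.
#'
#' @param p1,p2 Numeric length-2 vectors, fiducial endpoints in pixels.
#' @param known_length_mm Physical length of the fiducial in mm (> 0).
#' @return Object of class `pixel_calibration`: `mm_per_pixel`,
#'   `pixel_area_mm2` (= mm_per_pixel^2) and the fiducial used.
#' @export
#' @examples
#' compute_pixel_size(c(0, 0), c(3, 4), 10)$mm_per_pixel # 2
compute_pixel_size <- function(p1, p2, known_length_mm) {
  if (length(p1) != 2L || length(p2) != 2L || !is.numeric(p1) || !is.numeric(p2)) {
    stop_value("fiducial endpoints must be numeric (row, col) pairs")
  }
  if (!is_scalar_number(known_length_mm) || known_length_mm <= 0) {
    stop_value("known_length_mm must be a positive number")
  }
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) stop_value("degenerate fiducial: endpoints coincide")
  mm_per_pixel <- known_length_mm / d
  structure(list(mm_per_pixel = mm_per_pixel,
                 pixel_area_mm2 = mm_per_pixel^2,
                 fiducial = list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                                 known_length_mm = known_length_mm)),
            class = "pixel_calibration")
}

#' Build a calibration directly from a known scale
#'
#' @param mm_per_pixel Image scale in mm per pixel (> 0).
#' @return A `pixel_calibration` with no fiducial record.
#' @export
pixel_calibration <- function(mm_per_pixel) {
  if (!is_scalar_number(mm_per_pixel) || mm_per_pixel <= 0) {
    stop_value("mm_per_pixel must be a positive number")
  }
  structure(list(mm_per_pixel = mm_per_pixel,
                 pixel_area_mm2 = mm_per_pixel^2,
                 fiducial = NULL),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %.4f mm/px (%.4f mm^2/px)\n",
              x$mm_per_pixel, x$pixel_area_mm2))
  invisible(x)
}

#' Convert a pixel count to a physical area
#'
#' @param pixel_count Non-negative number of pixels.
#' @param cal A `pixel_calibration`.
#' @return Area in mm^2 (`pixel_count * pixel_area_mm2`).
#' @export
scaled_area <- function(pixel_count, cal) {
  stopifnot(inherits(cal, "pixel_calibration"))
  if (!is.numeric(pixel_count) || any(pixel_count < 0)) {
    stop_value("pixel_count must be non-negative")
  }
  pixel_count * cal$pixel_area_mm2
}

# parse the calibration block of a run config:
# {p1: [r,c], p2: [r,c], known_length_mm: x}  or  {mm_per_pixel: x}
calibration_from_config <- function(block) {
  if (!is.null(block$mm_per_pixel)) return(pixel_calibration(block$mm_per_pixel))
  if (is.null(block$p1) || is.null(block$p2) || is.null(block$known_length_mm)) {
    stop_value("calibration block needs either mm_per_pixel or p1/p2/known_length_mm")
  }
  compute_pixel_size(unlist(block$p1), unlist(block$p2), block$known_length_mm)
}
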