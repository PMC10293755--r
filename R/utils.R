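# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round doubles to the nearest IEEE single-precision value
#'
#' Used by the camera model: radiometric sensors emit digitized readings, and
#' quantizing to float32 makes the 32-bit TIFF round trip bit-exact.
#' @noRd
as_float32 <- function(x) {
  dims <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 "numeric", size = 4L, n = length(x))
  dim(out) <- dims
  out
}

#' Combine a base seed with a sample index (stays below 2^31)
#' @noRd
derive_seed <- function(base_seed, index) {
  bitwAnd(bitwXor(as.integer(base_seed), as.integer(index)), 0x7fffffffL)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_value <- function(...) stop(..., call. = FALSE)
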