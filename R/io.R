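# Sequence I/O: CSV frame directories and multi-page float TIFF stacks.
#
# csv_dir dialect: files frame_0001.csv, frame_0002.csv, ... in lexicographic
# order, comma-separated, no header, one temperature (degC) per cell,
# row-major. tiff_stack: one 32-bit-float page per frame, degC.
# An optional sidecar `meta.yaml` (flat `key: value` lines) carries
# frame_rate_hz, ambient_c, pressure_mmhg; for a TIFF stack the sidecar sits
# next to the file as `<stem>.meta.yaml`.

meta_sidecar_path <- function(path, format) {
  if (format == "csv_dir") file.path(path, "meta.yaml")
  else file.path(dirname(path), paste0(tools::file_path_sans_ext(basename(path)), ".meta.yaml"))
}

read_meta_sidecar <- function(file) {
  if (!file.exists(file)) return(list())
  out <- list()
  for (line in readLines(file, warn = FALSE)) {
    line <- sub("#.*$", "", line)
    if (!grepl(":", line, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", line))
    val <- trimws(sub("^[^:]*:", "", line))
    if (nzchar(key) && nzchar(val)) {
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.na(num)) val else num
    }
  }
  out
}

write_meta_sidecar <- function(meta, file) {
  lines <- vapply(names(meta), function(k) sprintf("%s: %s", k, format(meta[[k]])), character(1))
  writeLines(lines, file)
}

#' Read a thermogram sequence from disk
#'
#' @param path For `format = "csv_dir"`, a directory of `frame_%04d.csv`
#'   matrices; for `format = "tiff_stack"`, a multi-page 32-bit-float TIFF
#'   whose pixel values are degrees C.
#' @param format `"csv_dir"` or `"tiff_stack"`.
#' @param frame_rate_hz Acquisition rate. Taken from the `meta.yaml` sidecar
#'   when present; otherwise this argument is required (timestamps are
#'   synthesized as `index/frame_rate_hz`).
#' @return A [thermogram_sequence()]. Frames follow lexicographic filename /
#'   TIFF page order.
#' @export
read_sequence <- function(path, format = c("csv_dir", "tiff_stack"), frame_rate_hz = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_value("path does not exist: ", path)
  meta <- read_meta_sidecar(meta_sidecar_path(path, format))
  if (is.null(frame_rate_hz)) frame_rate_hz <- meta$frame_rate_hz
  if (is.null(frame_rate_hz)) {
    stop_value("frame_rate_hz is required (no meta.yaml sidecar found at ", path, ")")
  }
  mats <- if (format == "csv_dir") read_csv_frames(path) else read_tiff_float_stack(path)
  meta$frame_rate_hz <- NULL
  thermogram_sequence(mats, frame_rate_hz = frame_rate_hz, meta = meta)
}

read_csv_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop_value("no frame_NNNN.csv files in ", dir)
  lapply(files, read_csv_frame)
}

read_csv_frame <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_value("empty frame file: ", file)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop_value(sprintf("ragged matrix in %s: row %d has %d cells, expected %d",
                       file, bad, ncols[bad], ncols[1]))
  }
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1]
    r <- (flat - 1L) %/% ncols[1] + 1L
    c_ <- (flat - 1L) %% ncols[1] + 1L
    stop_value(sprintf("non-numeric cell in %s at row %d, col %d", file, r, c_))
  }
  matrix(vals, nrow = length(lines), ncol = ncols[1], byrow = TRUE)
}

#' Write a thermogram sequence to disk
#'
#' @param seq A [thermogram_sequence()].
#' @param path Output directory (`csv_dir`) or file (`tiff_stack`).
#' @param format `"csv_dir"` or `"tiff_stack"`.
#' @param decimals Decimal places for CSV output (>= 3; TIFF is always exact
#'   at float32 precision).
#' @param sidecar Write a `meta.yaml` sidecar with frame rate and metadata.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("csv_dir", "tiff_stack"),
                           decimals = 3L, sidecar = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "thermogram_sequence"))
  if (decimals < 3L) stop_value("CSV output requires >= 3 decimal places")
  mats <- lapply(seq$frames, function(f) f$values)
  if (format == "csv_dir") {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
      stop_value("cannot create directory ", path)
    }
    for (i in seq_along(mats)) {
      file <- file.path(path, sprintf("frame_%04d.csv", i))
      lines <- apply(mats[[i]], 1L, function(row) {
        paste(sprintf(paste0("%.", decimals, "f"), row), collapse = ",")
      })
      writeLines(lines, file)
    }
  } else {
    if (!dir.exists(dirname(path))) stop_value("cannot write to ", path)
    write_tiff_float_stack(mats, path)
  }
  if (sidecar) {
    meta <- seq$meta
    if (!is.na(seq$frame_rate_hz)) meta$frame_rate_hz <- seq$frame_rate_hz
    keep <- vapply(meta, function(v) is.numeric(v) || is.character(v), logical(1))
    write_meta_sidecar(meta[keep], meta_sidecar_path(path, format))
  }
  invisible(path)
}
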