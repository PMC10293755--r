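# Minimal multi-page TIFF codec for radiometric float stacks.
#
# Scope: baseline TIFF 6.0, grayscale, one 32-bit IEEE-float sample per
# pixel, uncompressed. This is the documented exchange format for
# temperature stacks (one page per frame, pixel values in degC); proprietary
# radiometric containers are out of scope and must be converted to this
# layout first. Writer emits little-endian single-strip pages; reader
# accepts either byte order and multi-strip pages (so stacks written by
# common scientific tools, e.g. tifffile, load too).

TIFF_TAG_WIDTH <- 256L
TIFF_TAG_LENGTH <- 257L
TIFF_TAG_BPS <- 258L
TIFF_TAG_COMPRESSION <- 259L
TIFF_TAG_PHOTOMETRIC <- 262L
TIFF_TAG_STRIP_OFFSETS <- 273L
TIFF_TAG_SPP <- 277L
TIFF_TAG_ROWS_PER_STRIP <- 278L
TIFF_TAG_STRIP_BYTES <- 279L
TIFF_TAG_SAMPLE_FORMAT <- 339L

# Write a list of numeric matrices as a multi-page float32 TIFF.
write_tiff_float_stack <- function(mats, path) {
  stopifnot(is.list(mats), length(mats) >= 1L)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  for (m in mats) {
    if (!is.matrix(m) || nrow(m) != h || ncol(m) != w) {
      stop_value("all pages must be matrices of identical size")
    }
  }
  n <- length(mats)
  data_bytes <- 4L * w * h
  ifd_bytes <- 2L + 10L * 12L + 4L
  block <- data_bytes + ifd_bytes
  page_data_offset <- function(i) 8L + (i - 1L) * block
  page_ifd_offset <- function(i) page_data_offset(i) + data_bytes

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wu16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wu32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, value) {
    wu16(tag); wu16(type); wu32(1L)
    if (type == 3L) { wu16(value); wu16(0L) } else wu32(value)
  }
  writeBin(charToRaw("II"), con)
  wu16(42L)
  wu32(page_ifd_offset(1L))
  for (i in seq_len(n)) {
    # pixel data, row-major
    writeBin(as.numeric(t(mats[[i]])), con, size = 4L, endian = "little")
    wu16(10L)  # entry count
    entry(TIFF_TAG_WIDTH, 4L, w)
    entry(TIFF_TAG_LENGTH, 4L, h)
    entry(TIFF_TAG_BPS, 3L, 32L)
    entry(TIFF_TAG_COMPRESSION, 3L, 1L)
    entry(TIFF_TAG_PHOTOMETRIC, 3L, 1L)
    entry(TIFF_TAG_STRIP_OFFSETS, 4L, page_data_offset(i))
    entry(TIFF_TAG_SPP, 3L, 1L)
    entry(TIFF_TAG_ROWS_PER_STRIP, 4L, h)
    entry(TIFF_TAG_STRIP_BYTES, 4L, data_bytes)
    entry(TIFF_TAG_SAMPLE_FORMAT, 3L, 3L)
    wu32(if (i < n) page_ifd_offset(i + 1L) else 0L)
  }
  invisible(path)
}

# Read a multi-page float32 TIFF into a list of numeric matrices.
read_tiff_float_stack <- function(path) {
  if (!file.exists(path)) stop_value("TIFF not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop_value("not a TIFF (file too short): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop_value("not a TIFF (bad byte-order mark): ", path))
  rint <- function(at, size) {
    readBin(raw[(at + 1L):(at + size)], "integer", size = size,
            signed = size > 2L, endian = endian)
  }
  if (rint(2L, 2L) != 42L) stop_value("not a TIFF (bad magic): ", path)

  # TIFF type code -> byte size (subset we care about; others are skipped)
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  read_values <- function(type, count, at) {
    sz <- type_size[[as.character(type)]]
    total <- sz * count
    src <- if (total <= 4L) at else rint(at, 4L)
    vapply(seq_len(count) - 1L, function(k) rint(src + k * sz, sz), integer(1))
  }

  pages <- list()
  ifd <- rint(4L, 4L)
  while (ifd != 0L) {
    n_entries <- rint(ifd, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      at <- ifd + 2L + (e - 1L) * 12L
      tag <- rint(at, 2L); type <- rint(at + 2L, 2L); count <- rint(at + 4L, 4L)
      if (!as.character(type) %in% names(type_size)) next  # RATIONAL/ASCII etc.
      tags[[as.character(tag)]] <- read_values(type, count, at + 8L)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_value("TIFF page missing required tag ", tag, ": ", path)
        default
      } else v
    }
    w <- need(TIFF_TAG_WIDTH); h <- need(TIFF_TAG_LENGTH)
    if (need(TIFF_TAG_COMPRESSION, 1L) != 1L) {
      stop_value("unsupported TIFF: compressed pages (expect uncompressed float32): ", path)
    }
    bps <- need(TIFF_TAG_BPS)
    if (length(bps) != 1L || bps != 32L || need(TIFF_TAG_SPP, 1L) != 1L) {
      stop_value("unsupported TIFF: expected one 32-bit sample per pixel: ", path)
    }
    if (need(TIFF_TAG_SAMPLE_FORMAT, 3L) != 3L) {
      stop_value("unsupported TIFF: SampleFormat is not IEEE float: ", path)
    }
    offsets <- need(TIFF_TAG_STRIP_OFFSETS)
    counts <- need(TIFF_TAG_STRIP_BYTES, 4L * w * h)
    if (length(counts) != length(offsets)) {
      stop_value("malformed TIFF: strip offset/byte-count mismatch: ", path)
    }
    buf <- raw(0)
    for (s in seq_along(offsets)) {
      buf <- c(buf, raw[(offsets[s] + 1L):(offsets[s] + counts[s])])
    }
    vals <- readBin(buf, "numeric", size = 4L, n = w * h, endian = endian)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd <- rint(ifd + 2L + n_entries * 12L, 4L)
  }
  if (length(pages) == 0L) stop_value("empty TIFF stack: ", path)
  pages
}
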