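## Minimal multi-page grayscale TIFF I/O.
##
## The movies this package consumes and emits are plain uncompressed
## grayscale stacks (one page per frame, one strip per page), which is the
## small corner of baseline TIFF implemented here. Little-endian only.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a grayscale image stack as a multi-page TIFF
#'
#' @param stack a single matrix or a list of integer matrices (frames), all
#'   the same size, values in `[0, 2^bits - 1]`. Matrices are stored with
#'   rows = image rows (y) and columns = image columns (x).
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path, bits = 8L) {
  if (is.matrix(stack)) stack <- list(stack)
  if (!length(stack)) stop_param("write_tiff: empty stack")
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop_param("write_tiff: bits must be 8 or 16")
  nr <- nrow(stack[[1]]); nc <- ncol(stack[[1]])
  bytes_px <- bits / 8L
  strip_len <- nr * nc * bytes_px
  n <- length(stack)

  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")

  # header
  writeBin(charToRaw("II"), con)
  w(42L, 2L)
  data_start <- 8L
  ifd_start <- data_start + n * strip_len
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  w(ifd_start, 4L)

  # pixel data, page after page, row-major as TIFF expects
  for (f in seq_len(n)) {
    m <- stack[[f]]
    if (nrow(m) != nr || ncol(m) != nc) stop_param("write_tiff: frames differ in size")
    v <- as.integer(t(m))
    if (anyNA(v) || min(v) < 0L || max(v) > (2^bits - 1)) {
      stop_param("write_tiff: pixel values outside [0, 2^bits - 1]")
    }
    w(v, bytes_px)
  }

  entry <- function(tag, type, count, value) {
    w(tag, 2L); w(type, 2L); w(count, 4L); w(value, 4L)
  }
  for (f in seq_len(n)) {
    w(n_entries, 2L)
    entry(TIFF_TAGS[["width"]], 4L, 1L, nc)
    entry(TIFF_TAGS[["length"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)   # BlackIsZero
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_start + (f - 1L) * strip_len)
    entry(TIFF_TAGS[["samples"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, strip_len)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L) # unsigned integer
    nxt <- if (f < n) ifd_start + f * ifd_size else 0L
    w(nxt, 4L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the uncompressed single-sample little-endian layout produced by
#' [write_tiff()] (and by common writers for plain grayscale stacks,
#' including multi-strip pages).
#'
#' @param path TIFF file.
#' @return list of integer matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop_param("read_tiff: not a TIFF file")
  if (!(rawToChar(raw[1:2]) == "II")) stop_param("read_tiff: only little-endian TIFF supported")
  int_at <- function(off, size, n = 1L) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = size == 4L)
  }
  magic <- int_at(2L, 2L)
  if (magic != 42L) stop_param("read_tiff: bad magic number")
  ifd <- int_at(4L, 4L)
  pages <- list()
  while (ifd != 0L) {
    n_entries <- int_at(ifd, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- int_at(off, 2L)
      type <- int_at(off + 2L, 2L)
      count <- int_at(off + 4L, 4L)
      size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(size)) next
      if (size * count <= 4L) {
        val <- int_at(off + 8L, size, count)
      } else {
        voff <- int_at(off + 8L, 4L)
        val <- int_at(voff, size, count)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    nc <- g(256L); nr <- g(257L)
    bits <- g(258L, 8L)[1]
    comp <- g(259L, 1L)
    if (comp != 1L) stop_param("read_tiff: compressed TIFF not supported")
    offs <- g(273L); cnts <- g(279L)
    bytes_px <- bits / 8L
    vals <- integer(0)
    for (s in seq_along(offs)) {
      vals <- c(vals, int_at(offs[s], bytes_px, cnts[s] / bytes_px))
    }
    if (bits == 8L) vals <- ifelse(vals < 0L, vals + 256L, vals)
    if (bits == 16L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    ifd <- int_at(ifd + 2L + n_entries * 12L, 4L)
  }
  pages
}
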