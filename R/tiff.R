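# Minimal baseline TIFF support: little-endian, uncompressed, grayscale,
# one strip per page, multi-page via the IFD chain.  Covers exactly what the
# package writes (32-bit IEEE float or 16-bit unsigned) plus 8-bit reads.
# No external TIFF library is assumed.

TIFF_TAG <- list(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, PhotometricInterpretation = 262L,
  StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
  StripByteCounts = 279L, SampleFormat = 339L
)

#' Write a 3D array as a multi-page grayscale TIFF
#'
#' Pages are the first array dimension (z); each page is written as a single
#' uncompressed strip, row-major (y rows of x samples). Data are stored as
#' 32-bit IEEE floats unless `bits = 16`, in which case values must be
#' non-negative integers below 2^16.
#'
#' @param arr numeric 3D array, dimension `(z, y, x)`; a matrix is promoted
#'   to a single page.
#' @param path output file path.
#' @param bits 64 or 32 (IEEE float) or 16 (unsigned integer); 64 gives
#'   bit-exact round trips of R doubles.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(arr, path, bits = 64L) {
  if (is.matrix(arr)) arr <- array(arr, c(1L, dim(arr)))
  stopifnot(is.array(arr), length(dim(arr)) == 3L, bits %in% c(16L, 32L, 64L))
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (bits == 16L) {
    if (any(arr < 0) || any(arr != round(arr)) || any(arr >= 65536))
      stop("16-bit TIFF requires integer values in [0, 65535]")
  }
  bytes_per <- bits / 8L
  strip_bytes <- nx * ny * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                      # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  # layout: header(8) | page1 strip | page1 IFD | page2 strip | ...
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  writeBin(as.integer(offset + strip_bytes), con, size = 4, endian = "little")
  sample_format <- if (bits >= 32L) 3L else 1L        # 3 = IEEE float
  for (z in seq_len(nz)) {
    page <- t(arr[z, , , drop = TRUE])                # -> x fastest (row-major rows of y)
    # page is nx x ny; write row-major: for each y row, nx samples
    vals <- as.vector(page)                           # column-major of t() == rows of original
    if (bits == 64L) {
      writeBin(as.numeric(vals), con, size = 8, endian = "little")
    } else if (bits == 32L) {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(vals), con, size = 2, endian = "little")
    }
    strip_off <- offset
    ifd_off <- strip_off + strip_bytes
    # next page: strip immediately after this IFD, its IFD after that strip
    next_strip <- ifd_off + ifd_size
    next_off <- if (z < nz) next_strip + strip_bytes else 0L
    writeBin(n_entries, con, size = 2, endian = "little")
    wr_entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    wr_entry(TIFF_TAG$ImageWidth, 4L, 1L, nx)
    wr_entry(TIFF_TAG$ImageLength, 4L, 1L, ny)
    wr_entry(TIFF_TAG$BitsPerSample, 3L, 1L, bits)
    wr_entry(TIFF_TAG$Compression, 3L, 1L, 1L)
    wr_entry(TIFF_TAG$PhotometricInterpretation, 3L, 1L, 1L)
    wr_entry(TIFF_TAG$StripOffsets, 4L, 1L, strip_off)
    wr_entry(TIFF_TAG$SamplesPerPixel, 3L, 1L, 1L)
    wr_entry(TIFF_TAG$RowsPerStrip, 4L, 1L, ny)
    wr_entry(TIFF_TAG$StripByteCounts, 4L, 1L, strip_bytes)
    wr_entry(TIFF_TAG$SampleFormat, 3L, 1L, sample_format)
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
    offset <- next_strip
  }
  invisible(path)
}

read_uint <- function(raw, pos, n) {
  # little-endian unsigned integer of n bytes at 1-based pos
  b <- as.integer(raw[pos:(pos + n - 1L)])
  sum(b * 256^(seq_len(n) - 1L))
}

#' Read a multi-page grayscale TIFF into a 3D array
#'
#' Supports baseline little- or big-endian, uncompressed, single-sample
#' grayscale pages of 8/16-bit unsigned or 32-bit float data; all pages must
#' share one shape.
#'
#' @param path TIFF file path.
#' @return numeric array `(z, y, x)`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  byte_order <- rawToChar(raw[1:2])
  if (!byte_order %in% c("II", "MM")) stop("not a TIFF file: ", path)
  le <- byte_order == "II"
  u <- function(pos, n) {
    b <- as.integer(raw[pos:(pos + n - 1L)])
    if (!le) b <- rev(b)
    sum(b * 256^(seq_len(n) - 1L))
  }
  if (u(3L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- u(5L, 4L)
  pages <- list()
  while (ifd != 0L) {
    n_ent <- u(ifd + 1L, 2L)
    tags <- list()
    for (i in seq_len(n_ent)) {
      e <- ifd + 2L + (i - 1L) * 12L + 1L
      tag <- u(e, 2L); type <- u(e + 2L, 2L); count <- u(e + 4L, 4L)
      vsz <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
      if (vsz * count <= 4L) {
        val <- u(e + 8L, vsz)
      } else {
        off <- u(e + 8L, 4L)
        val <- vapply(seq_len(count), function(k) u(off + (k - 1L) * vsz + 1L, vsz), 0)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    nx <- g(256L); ny <- g(257L)
    bits <- g(258L, 1L)[1]
    comp <- g(259L, 1L)
    fmt <- g(339L, 1L)[1]
    spp <- g(277L, 1L)
    if (comp != 1L) stop("only uncompressed TIFF supported")
    if (spp != 1L) stop("only single-sample grayscale TIFF supported")
    offs <- g(273L); cnts <- g(279L)
    strip <- raw(0)
    for (k in seq_along(offs))
      strip <- c(strip, raw[(offs[k] + 1L):(offs[k] + cnts[k])])
    endian <- if (le) "little" else "big"
    vals <- if (fmt == 3L && bits == 64L) {
      readBin(strip, "numeric", n = nx * ny, size = 8, endian = endian)
    } else if (fmt == 3L && bits == 32L) {
      readBin(strip, "numeric", n = nx * ny, size = 4, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 16L) {
      readBin(strip, "integer", n = nx * ny, size = 2, signed = FALSE, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 8L) {
      as.integer(strip[seq_len(nx * ny)])
    } else stop("unsupported TIFF sample format (bits=", bits, ", fmt=", fmt, ")")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = nx, ncol = ny)  # x fastest
    ifd <- u(ifd + 2L + n_ent * 12L + 1L, 4L)
  }
  shapes <- vapply(pages, dim, integer(2))
  if (nrow(unique(t(shapes))) != 1L) stop("non-uniform page shapes in ", path)
  nx <- shapes[1, 1]; ny <- shapes[2, 1]; nz <- length(pages)
  out <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) out[z, , ] <- t(pages[[z]])
  out
}
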