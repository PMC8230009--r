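# Minimal baseline-TIFF codec for grayscale scientific stacks.
#
# The CRAN `tiff` package stores images as [0,1]-scaled integer samples and
# cannot write (or read back unscaled) IEEE-float pages, which breaks the
# exact round-trip contract volume IO needs. This codec writes uncompressed
# single-sample (grayscale) multi-page TIFFs with 8/16-bit unsigned or 32-bit
# float samples, and reads the same subset back bit-exactly. Anything outside
# that subset (compression, tiles, palettes, BigTIFF) is signalled as
# `xgalvox_tiff_unsupported` so callers can fall back to `tiff::readTIFF`.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, spp = 277L,
                 rows_per_strip = 278L, strip_bytes = 279L,
                 planar = 284L, sample_format = 339L, tile_width = 322L)

# ---- writing ---------------------------------------------------------------

#' Write a multi-page grayscale TIFF (internal codec)
#'
#' @param pages list of numeric matrices, all the same shape. For `"u8"` and
#'   `"u16"` values must already be integers in range.
#' @param path output file path.
#' @param sample_type one of `"u8"`, `"u16"`, `"f32"`.
#' @keywords internal
#' @noRd
tiff_codec_write <- function(pages, path, sample_type) {
  stopifnot(length(pages) >= 1L,
            all(vapply(pages, function(p) identical(dim(p), dim(pages[[1L]])),
                       logical(1))))
  bits <- switch(sample_type, u8 = 8L, u16 = 16L, f32 = 32L,
                 stop("unknown sample type", call. = FALSE))
  fmt <- if (sample_type == "f32") 3L else 1L
  bytes_per <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  # layout per page: pixel data then its IFD; the header therefore points at
  # 8 + <page 1 data bytes>
  first_ifd <- 8L + nrow(pages[[1L]]) * ncol(pages[[1L]]) * bytes_per
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(first_ifd), con, size = 4L, endian = "little")
  offset <- 8L

  wr_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT, inline (count 1)
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {           # LONG, inline (count 1)
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }

  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    data_bytes <- h * w * bytes_per
    data_off <- offset
    # pixel data, row-major
    vals <- as.vector(t(m))
    if (sample_type == "f32") {
      writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(vals), con, size = bytes_per, endian = "little",
               useBytes = TRUE)
    }
    ifd_off <- data_off + data_bytes
    writeBin(n_tags, con, size = 2L, endian = "little")
    wr_entry(TIFF_TAG$width, 4L, 1L, w)
    wr_entry(TIFF_TAG$length, 4L, 1L, h)
    wr_entry(TIFF_TAG$bits, 3L, 1L, bits)
    wr_entry(TIFF_TAG$compression, 3L, 1L, 1L)
    wr_entry(TIFF_TAG$photometric, 3L, 1L, 1L)
    wr_entry(TIFF_TAG$strip_offsets, 4L, 1L, data_off)
    wr_entry(TIFF_TAG$spp, 3L, 1L, 1L)
    wr_entry(TIFF_TAG$rows_per_strip, 4L, 1L, h)
    wr_entry(TIFF_TAG$strip_bytes, 4L, 1L, data_bytes)
    wr_entry(TIFF_TAG$sample_format, 3L, 1L, fmt)
    # next page: its data block first, then its IFD
    next_ifd <- if (p < length(pages)) ifd_off + ifd_size + data_bytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

unsupported <- function(msg) {
  stop(structure(class = c("xgalvox_tiff_unsupported", "error", "condition"),
                 list(message = msg, call = NULL)))
}

rd_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[(off + 1L):(off + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1L))
}

#' Read a multi-page grayscale TIFF (internal codec)
#'
#' @return list of numeric matrices (one per page).
#' @keywords internal
#' @noRd
tiff_codec_read <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) unsupported("file too short to be a TIFF")
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   unsupported("not a TIFF file"))
  if (rd_uint(raw, 2L, 2L, endian) != 42L)
    unsupported("not a classic TIFF (BigTIFF or corrupt)")
  ifd_off <- rd_uint(raw, 4L, 4L, endian)

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  read_values <- function(type, count, entry_off) {
    sz <- type_size[as.character(type)]
    if (is.na(sz)) return(NULL)
    total <- sz * count
    off <- if (total <= 4L) entry_off + 8L else
      rd_uint(raw, entry_off + 8L, 4L, endian)
    vapply(seq_len(count) - 1L,
           function(i) rd_uint(raw, off + i * sz, sz, endian), numeric(1))
  }

  pages <- list()
  while (ifd_off != 0L) {
    n <- rd_uint(raw, ifd_off, 2L, endian)
    tags <- list()
    for (i in seq_len(n)) {
      eoff <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_uint(raw, eoff, 2L, endian)
      type <- rd_uint(raw, eoff + 2L, 2L, endian)
      count <- rd_uint(raw, eoff + 4L, 4L, endian)
      tags[[as.character(tag)]] <- read_values(type, count, eoff)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!is.null(g(TIFF_TAG$tile_width))) unsupported("tiled TIFF")
    if (g(TIFF_TAG$compression, 1L)[1L] != 1L)
      unsupported("compressed TIFF")
    spp <- g(TIFF_TAG$spp, 1L)[1L]
    if (spp != 1L)
      stop("multichannel (RGB) TIFF pages are not grayscale volumes",
           call. = FALSE)
    if (g(TIFF_TAG$planar, 1L)[1L] != 1L) unsupported("planar TIFF")
    w <- g(TIFF_TAG$width)[1L]; h <- g(TIFF_TAG$length)[1L]
    if (is.null(w) || is.null(h)) unsupported("missing geometry tags")
    bits <- g(TIFF_TAG$bits, 1L)[1L]
    fmt <- g(TIFF_TAG$sample_format, 1L)[1L]
    if (!(bits %in% c(8, 16, 32))) unsupported("unsupported bit depth")
    if (!(fmt %in% c(1, 3))) unsupported("unsupported sample format")
    if (fmt == 3 && bits != 32) unsupported("unsupported float depth")
    if (fmt == 1 && bits == 32) unsupported("32-bit integer samples")
    strip_off <- g(TIFF_TAG$strip_offsets)
    strip_len <- g(TIFF_TAG$strip_bytes)
    if (is.null(strip_off) || is.null(strip_len))
      unsupported("missing strip tags")
    payload <- raw(0)
    for (s in seq_along(strip_off)) {
      payload <- c(payload,
                   raw[(strip_off[s] + 1L):(strip_off[s] + strip_len[s])])
    }
    n_px <- w * h
    vals <- if (fmt == 3) {
      readBin(payload, "numeric", n = n_px, size = 4L, endian = endian)
    } else {
      readBin(payload, "integer", n = n_px, size = bits %/% 8L,
              signed = FALSE, endian = endian)
    }
    if (length(vals) < n_px) unsupported("truncated pixel data")
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = h,
                                          ncol = w, byrow = TRUE)
    ifd_off <- rd_uint(raw, ifd_off + 2L + n * 12L, 4L, endian)
  }
  if (!length(pages)) unsupported("TIFF with zero pages")
  pages
}
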