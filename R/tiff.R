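# Minimal baseline TIFF I/O.
#
# No TIFF package ships with this R library, so the subset of baseline TIFF
# the pipeline needs is implemented here: uncompressed grayscale, 8 or 16
# bits per sample, one or more pages (pages = channels). The writer emits
# little-endian single-strip pages; the reader additionally accepts
# big-endian files and multi-strip layouts.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write a grayscale (multi-page) TIFF
#'
#' Values are rounded and clamped to the unsigned range of `bits`. A list of
#' matrices is written as a multi-page file, one page per channel.
#'
#' @param image numeric/integer matrix, or list of same-shaped matrices.
#' @param path output file.
#' @param bits bits per sample, 8 or 16.
#' @return invisibly, `path`.
#' @export
write_tiff <- function(image, path, bits = 16L) {
  if (is.matrix(image)) image <- list(image)
  stopifnot(length(image) >= 1, all(vapply(image, is.matrix, logical(1))),
            bits %in% c(8L, 16L))
  vmax <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset: filled in after layout is known
  writeBin(8L, con, size = 4, endian = "little")
  offset <- 8L
  n_pages <- length(image)
  for (p in seq_len(n_pages)) {
    m <- image[[p]]
    h <- nrow(m); w <- ncol(m)
    vals <- as.integer(pmin(pmax(round(t(m)), 0), vmax))  # row-major
    data_off <- offset
    nbytes <- length(vals) * (bits / 8L)
    writeBin(vals, con, size = bits / 8L, endian = "little")
    ifd_off <- data_off + nbytes
    if (ifd_off %% 2 == 1) {  # IFDs must be word-aligned
      writeBin(as.raw(0), con)
      ifd_off <- ifd_off + 1L
    }
    entries <- list(
      list(TIFF_TAGS[["ImageWidth"]], 3L, 1L, w),
      list(TIFF_TAGS[["ImageLength"]], 3L, 1L, h),
      list(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bits),
      list(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off),
      list(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      list(TIFF_TAGS[["RowsPerStrip"]], 3L, 1L, h),
      list(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, nbytes),
      list(TIFF_TAGS[["SampleFormat"]], 3L, 1L, 1L))
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(as.integer(e[[1]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[[2]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[[3]]), con, size = 4, endian = "little")
      if (e[[2]] == 3L) {  # SHORT packed into 4-byte value slot
        writeBin(as.integer(e[[4]]), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(e[[4]]), con, size = 4, endian = "little")
      }
    }
    ifd_end <- ifd_off + 2L + 12L * length(entries) + 4L
    next_ifd <- if (p < n_pages) {
      # the next IFD sits after the next page's pixel data (plus alignment)
      nb <- length(image[[p + 1]]) * (bits / 8L)
      ifd_end + nb + (ifd_end + nb) %% 2L
    } else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_end
    if (p == 1) first_ifd <- ifd_off
  }
  seek(con, 4, rw = "write")
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  invisible(path)
}

read_uint <- function(raw, off, size, endian) {
  bytes <- as.integer(raw[(off + 1):(off + size)])
  if (endian == "big") bytes <- rev(bytes)
  sum(bytes * 256^(seq_len(size) - 1))
}

#' Read a grayscale (multi-page) TIFF
#'
#' Supports uncompressed single-sample baseline TIFF, 8 or 16 bits, either
#' byte order, single- or multi-strip.
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stopf("'%s' is not a TIFF file", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
  else if (rawToChar(raw[1:2]) == "MM") "big"
  else stopf("'%s' is not a TIFF file", path)
  if (read_uint(raw, 2, 2, endian) != 42) stopf("'%s' is not a TIFF file", path)
  ifd <- read_uint(raw, 4, 4, endian)
  pages <- list()
  while (ifd != 0) {
    n <- read_uint(raw, ifd, 2, endian)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + 12 * (k - 1)
      tag <- read_uint(raw, e, 2, endian)
      type <- read_uint(raw, e + 2, 2, endian)
      count <- read_uint(raw, e + 4, 4, endian)
      tsize <- c(1, 1, 2, 4, 8)[type]
      if (is.na(tsize)) next
      total <- tsize * count
      voff <- if (total <= 4) e + 8 else read_uint(raw, e + 8, 4, endian)
      vals <- vapply(seq_len(count) - 1,
                     function(i) read_uint(raw, voff + i * tsize, tsize, endian),
                     numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) {
        if (is.null(default)) stopf("'%s': missing TIFF tag %s", path, tag)
        default
      } else v
    }
    if (need("Compression", 1) != 1)
      stopf("'%s': only uncompressed TIFF is supported", path)
    if (need("SamplesPerPixel", 1) != 1)
      stopf("'%s': only single-sample (grayscale) TIFF is supported", path)
    w <- need("ImageWidth"); h <- need("ImageLength")
    bits <- need("BitsPerSample", 1)
    if (!bits %in% c(8, 16)) stopf("'%s': unsupported bit depth %d", path, bits)
    offs <- need("StripOffsets")
    counts <- need("StripByteCounts", w * h * bits / 8)
    bytes <- unlist(lapply(seq_along(offs), function(s)
      raw[(offs[s] + 1):(offs[s] + counts[s])]))
    vals <- readBin(bytes, "integer", n = w * h, size = bits / 8,
                    signed = FALSE, endian = endian)
    pages[[length(pages) + 1]] <- matrix(as.numeric(vals), nrow = h,
                                         ncol = w, byrow = TRUE)
    ifd <- read_uint(raw, ifd + 2 + 12 * n, 4, endian)
  }
  pages
}

#' Read a multichannel TIFF as named single-channel matrices
#'
#' Pages of the file are interpreted as channels, in order, and named with
#' `channel_names`. The channel count must match the page count exactly.
#'
#' @param path TIFF file.
#' @param channel_names character vector, one name per expected channel.
#' @return named list of numeric matrices.
#' @export
read_multichannel_image <- function(path, channel_names) {
  if (!file.exists(path)) stopf("image file '%s' does not exist", path)
  pages <- read_tiff(path)
  if (length(pages) != length(channel_names))
    stopf("'%s' has %d channel(s) but %d name(s) were requested: %s",
          path, length(pages), length(channel_names),
          paste(channel_names, collapse = ", "))
  names(pages) <- channel_names
  pages
}
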