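# Minimal baseline TIFF I/O (little-endian, uncompressed, single-channel
# grayscale, 8- or 16-bit, multi-page). Covers the stacks written by the
# synthetic generator and typical uncompressed microscopy exports; anything
# fancier (compression, tiles, RGB) is rejected with a clear error.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples_per_px = 277L,
               rows_per_strip = 278L, strip_byte_counts = 279L,
               sample_format = 339L)

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' @param frames list of numeric matrices, or a 3-D array (rows, cols, frames).
#'   Values are clamped to \[0, 65535\] and rounded to integers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path) {
  frames <- as_frame_list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)  # header; first IFD at 8
  offset <- 8L
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    nr <- nrow(fr); nc <- ncol(fr)
    nbytes <- nr * nc * 2L
    data_off <- offset + ifd_size
    next_ifd <- if (i < length(frames)) data_off + nbytes else 0L
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count); w32(value)
    }
    w16(n_entries)
    entry(256L, 3L, 1L, nc)            # ImageWidth
    entry(257L, 3L, 1L, nr)            # ImageLength
    entry(258L, 3L, 1L, 16L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)      # StripOffsets
    entry(277L, 3L, 1L, 1L)            # SamplesPerPixel
    entry(278L, 3L, 1L, nr)            # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)        # StripByteCounts
    entry(339L, 3L, 1L, 1L)           # SampleFormat: unsigned int
    w32(next_ifd)
    px <- round(pmin(pmax(t(fr), 0), 65535))  # row-major scanlines
    writeBin(as.integer(px), con, size = 2, endian = "little")
    offset <- next_ifd
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF stack
#'
#' @param path TIFF file path.
#' @return list of numeric matrices (one per page).
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop("read_tiff_stack: not a TIFF file")
  magic <- rawToChar(raw_all[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("read_tiff_stack: not a TIFF file"))
  u16 <- function(off) readBin(raw_all[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw_all[(off + 1):(off + 4)], "integer",
                               size = 4, endian = endian)
  if (u16(2L) != 42L) stop("read_tiff_stack: not a TIFF file")
  ifd <- u32(4L)
  frames <- list()
  while (ifd != 0L) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2L + (k - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      val <- if (type == 3L && count == 1L) u16(e + 8L) else u32(e + 8L)
      # multi-valued offsets: read the first count values from the pointer
      if (count > 1L && tag %in% c(273L, 279L, 258L)) {
        ptr <- u32(e + 8L)
        sz <- if (type == 3L) 2L else 4L
        rd <- if (type == 3L) u16 else u32
        val <- vapply(seq_len(count) - 1L, function(j) rd(ptr + j * sz), 0)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    nc <- g(256L); nr <- g(257L)
    bits <- g(258L, 1L)[1]
    if (!is.null(g(259L)) && g(259L) != 1L)
      stop("read_tiff_stack: only uncompressed TIFF is supported")
    if (g(277L, 1L) != 1L)
      stop("read_tiff_stack: only single-channel grayscale is supported")
    if (!bits %in% c(8L, 16L))
      stop("read_tiff_stack: only 8- or 16-bit samples are supported")
    offs <- g(273L); counts <- g(279L, nr * nc * bits / 8)
    buf <- raw(0)
    for (s in seq_along(offs)) {
      buf <- c(buf, raw_all[(offs[s] + 1):(offs[s] + counts[s])])
    }
    px <- readBin(buf, "integer", n = nr * nc, size = bits / 8L,
                  signed = FALSE, endian = endian)
    frames[[length(frames) + 1L]] <- matrix(px, nrow = nr, ncol = nc,
                                            byrow = TRUE)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  frames
}

as_frame_list <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(is.list(frames), length(frames) > 0L,
            all(vapply(frames, is.matrix, TRUE)))
  frames
}
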