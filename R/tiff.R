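# Minimal baseline-TIFF I/O (uncompressed, 16-bit grayscale, little-endian,
# one strip per page). No TIFF package is available in the target
# environment; this covers exactly what the simulator writes.

#' Write a multi-page 16-bit grayscale TIFF
#'
#' @param frames list of integer/numeric matrices (rows = y, cols = x) with
#'   values in `[0, 65535]`, or a single matrix.
#' @param path output file path.
#' @param pixel_size_um pixel size recorded in the image description tag.
#' @return invisibly, `path`.
#' @export
write_tiff_stack <- function(frames, path, pixel_size_um = 0.16) {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); # header; IFD offset patched below
  desc <- sprintf("toccslr pixel_size_um=%g", pixel_size_um)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  offset <- 8L
  w4(offset)
  n_tags <- 8L
  for (fi in seq_along(frames)) {
    img <- frames[[fi]]
    h <- nrow(img); w <- ncol(img)
    nbytes <- 2L * h * w
    ifd_size <- 2L + n_tags * 12L + 4L
    data_off <- offset + ifd_size
    desc_off <- data_off + nbytes
    next_ifd <- desc_off + length(desc_raw)
    if (next_ifd %% 2L == 1L) next_ifd <- next_ifd + 1L
    tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
    w2(n_tags)
    tag(256L, 3L, 1L, w)            # ImageWidth
    tag(257L, 3L, 1L, h)            # ImageLength
    tag(258L, 3L, 1L, 16L)          # BitsPerSample
    tag(259L, 3L, 1L, 1L)           # Compression: none
    tag(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    tag(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
    tag(273L, 4L, 1L, data_off)     # StripOffsets
    tag(279L, 4L, 1L, nbytes)       # StripByteCounts
    w4(if (fi < length(frames)) next_ifd else 0L)
    # pixel data, row-major
    vals <- as.integer(round(t(img)))
    vals <- pmin(65535L, pmax(0L, vals))
    writeBin(vals, con, size = 2, endian = "little")
    writeBin(desc_raw, con)
    pos <- desc_off + length(desc_raw)
    if (pos %% 2L == 1L) { writeBin(as.raw(0), con); pos <- pos + 1L }
    offset <- pos
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff_stack()]
#'
#' Supports uncompressed 16-bit grayscale little-endian files only.
#'
#' @param path file path.
#' @return list of integer matrices with attribute `pixel_size_um` when
#'   recorded.
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  r2 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  r4 <- function(off) sum(as.integer(raw_all[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw_all[1:2]) != "II" || r2(2L) != 42L)
    stop("read_tiff_stack: not a little-endian TIFF")
  ifd <- r4(4L)
  frames <- list()
  px <- NA_real_
  while (ifd != 0L) {
    n <- r2(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      base <- ifd + 2L + (k - 1L) * 12L
      id <- r2(base); typ <- r2(base + 2L); cnt <- r4(base + 4L)
      val <- r4(base + 8L)
      if (typ == 3L && cnt == 1L) val <- r2(base + 8L)
      tags[[as.character(id)]] <- list(type = typ, count = cnt, value = val)
    }
    w <- tags[["256"]]$value; h <- tags[["257"]]$value
    if (tags[["258"]]$value != 16L || tags[["259"]]$value != 1L)
      stop("read_tiff_stack: only uncompressed 16-bit supported")
    off <- tags[["273"]]$value
    nb <- tags[["279"]]$value
    v <- readBin(raw_all[(off + 1L):(off + nb)], "integer", n = nb / 2L,
                 size = 2, signed = FALSE, endian = "little")
    frames[[length(frames) + 1L]] <- t(matrix(v, w, h))
    if (!is.null(tags[["270"]])) {
      d <- tags[["270"]]
      txt <- rawToChar(raw_all[(d$value + 1L):(d$value + d$count - 1L)])
      m <- regmatches(txt, regexec("pixel_size_um=([0-9.eE+-]+)", txt))[[1L]]
      if (length(m) == 2L) px <- as.numeric(m[2L])
    }
    ifd <- r4(ifd + 2L + n * 12L)
  }
  attr(frames, "pixel_size_um") <- px
  frames
}
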