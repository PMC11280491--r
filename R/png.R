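# Minimal 8-bit PNG codec (non-interlaced, grayscale / RGB / with alpha),
# enough for challenge-style images and masks. Compression, CRC32 and
# scanline unfiltering are delegated to zlib through the compiled kernels.

PNG_SIG <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))

u32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(floor(x / 2^24) %% 256, floor(x / 2^16) %% 256,
           floor(x / 2^8) %% 256, x %% 256))
}

be_u32 <- function(r) {
  sum(as.numeric(r) * c(2^24, 2^16, 2^8, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(cpp_crc32(body)))
}

#' Write an image as an 8-bit PNG
#'
#' @param img numeric matrix (grayscale) or `H x W x 3` array with values in
#'   `[0, 1]`; values are clipped and quantised to 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  stopifnot(length(dim(img)) == 3, dim(img)[3] %in% c(1L, 3L))
  H <- dim(img)[1]; W <- dim(img)[2]; ch <- dim(img)[3]
  v <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  dim(v) <- dim(img)
  # interleave channels within each row, rows top to bottom, filter byte 0
  px <- aperm(v, c(3, 2, 1)) # (channel, col, row)
  rows <- matrix(as.raw(px), nrow = ch * W, ncol = H)
  raw_dat <- as.raw(rbind(matrix(as.raw(0), 1, H), rows))
  idat <- cpp_zlib_compress(raw_dat, 6L)
  ihdr <- c(u32_be(W), u32_be(H), as.raw(c(8, if (ch == 3) 2 else 0, 0, 0, 0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(PNG_SIG, png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
             png_chunk("IEND", raw(0))), con)
  invisible(path)
}

#' Read an 8-bit PNG
#'
#' Supports non-interlaced 8-bit grayscale, RGB, and their alpha variants.
#'
#' @param path PNG file path.
#' @return integer array `H x W x channels` with values 0..255.
#' @export
read_png <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 8 || !identical(r[1:8], PNG_SIG))
    stop("not a PNG file: ", path)
  pos <- 9L
  width <- height <- bitdepth <- coltype <- interlace <- NULL
  idat <- list()
  while (pos + 8 <= length(r)) {
    len <- be_u32(r[pos:(pos + 3)])
    type <- rawToChar(r[(pos + 4):(pos + 7)])
    data <- if (len > 0) r[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      width <- be_u32(data[1:4]); height <- be_u32(data[5:8])
      bitdepth <- as.integer(data[9]); coltype <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(width)) stop("corrupt PNG (no IHDR): ", path)
  if (bitdepth != 8) stop("unsupported PNG bit depth ", bitdepth, " (only 8)")
  if (interlace != 0) stop("interlaced PNG not supported")
  ch <- switch(as.character(coltype), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop("unsupported PNG colour type ", coltype))
  rowbytes <- as.integer(width * ch)
  flt <- cpp_zlib_uncompress(do.call(c, idat), height * (rowbytes + 1))
  dat <- cpp_png_unfilter(flt, as.integer(height), rowbytes, ch)
  px <- as.integer(dat)
  dim(px) <- c(ch, width, height)
  aperm(px, c(3, 2, 1)) # H x W x ch
}
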