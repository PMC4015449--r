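#' Read a microscopy image as an 8-bit grayscale matrix
#'
#' Supported formats: PNG and JPEG (via the \pkg{png} and \pkg{jpeg}
#' packages), uncompressed 8-bit and 24-bit BMP, and plain/raw PGM/PPM.
#' Color images are collapsed to luminance with [to_gray()]; inputs with
#' more than 8 bits per channel are rescaled linearly onto \[0, 255\].
#' Single-page TIFF is not supported in this build (no reader available);
#' such files raise an error that batch drivers report as "skipped".
#'
#' @param path Path to an image file; format is chosen by extension.
#' @return An integer matrix (rows x cols) of intensities in \[0, 255\].
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(12), 3, 4), f)
#' img <- read_gray_image(f)
#' dim(img)
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    # readPNG/readJPEG return values on [0, 1] regardless of source depth
    png  = png::readPNG(path) * 255,
    jpg  = ,
    jpeg = jpeg::readJPEG(path) * 255,
    # own readers already return values on [0, 255]
    bmp  = .read_bmp(path),
    pgm  = ,
    ppm  = ,
    pnm  = .read_pnm(path),
    tif  = ,
    tiff = stop("TIFF input is not supported by this build; ",
                "convert to PNG first"),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L) {
    arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) {
    arr <- arr[, , 1L]
  }
  to_gray(arr)
}

#' Write an 8-bit grayscale matrix as PNG
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

# Minimal reader for uncompressed Windows BMP (8-bit palette or 24-bit).
# Rows are stored bottom-up, padded to 4-byte boundaries.
.read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u16 <- function(i) as.integer(raw[i + 1L]) + 256L * as.integer(raw[i + 2L])
  u32 <- function(i) sum(as.numeric(raw[i + 1:4]) * 256^(0:3))
  offset <- u32(10L)
  hdr_size <- u32(14L)
  if (hdr_size < 40) stop("unsupported BMP header")
  width <- u32(18L); height <- u32(22L)
  if (height > 2^31) stop("top-down BMP not supported")
  bpp <- u16(28L)
  compression <- u32(30L)
  if (compression != 0) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("unsupported BMP bit depth: ", bpp)

  row_bytes <- ((width * bpp / 8 + 3) %/% 4) * 4
  px <- raw[(offset + 1L):(offset + row_bytes * height)]
  m <- matrix(as.integer(px), nrow = row_bytes, ncol = height)
  if (bpp == 24L) {
    b <- m[seq(1L, 3L * width, by = 3L), , drop = FALSE]
    g <- m[seq(2L, 3L * width, by = 3L), , drop = FALSE]
    r <- m[seq(3L, 3L * width, by = 3L), , drop = FALSE]
    out <- array(0, dim = c(height, width, 3L))
    out[, , 1] <- t(r)[height:1, , drop = FALSE]
    out[, , 2] <- t(g)[height:1, , drop = FALSE]
    out[, , 3] <- t(b)[height:1, , drop = FALSE]
    out
  } else {
    # palette: 4 bytes per entry (B, G, R, 0) right after the DIB header
    pal_at <- 14L + hdr_size
    n_pal <- (offset - pal_at) %/% 4L
    pal <- matrix(as.integer(raw[(pal_at + 1L):(pal_at + 4L * n_pal)]),
                  nrow = 4L)
    lum <- round(0.299 * pal[3L, ] + 0.587 * pal[2L, ] + 0.114 * pal[1L, ])
    idx <- m[seq_len(width), , drop = FALSE]
    matrix(lum[t(idx)[height:1, , drop = FALSE] + 1L], nrow = height)
  }
}

# Plain (P1-P3) and raw (P4-P6) netpbm readers; 16-bit samples rescaled.
.read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM flavor: ", magic)
  tok <- character(0)
  # header tokens: width height maxval (comments start with '#')
  while (length(tok) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r")) break
      }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (!grepl("[0-9]", ch)) break
        num <- paste0(num, ch)
      }
      tok <- c(tok, num)
    }
  }
  width <- as.integer(tok[1]); height <- as.integer(tok[2])
  maxval <- as.integer(tok[3])
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- width * height * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n))
  } else {
    readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  }
  vals <- vals / maxval * 255
  if (nch == 1L) {
    matrix(vals, nrow = height, byrow = TRUE)
  } else {
    out <- array(0, dim = c(height, width, 3L))
    for (k in 1:3)
      out[, , k] <- matrix(vals[seq(k, n, by = 3L)], nrow = height,
                           byrow = TRUE)
    out
  }
}
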