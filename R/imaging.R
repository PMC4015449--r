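#' Convert a pixel array to 8-bit grayscale
#'
#' RGB input is collapsed with the standard luminance weights
#' (0.299, 0.587, 0.114), rounded to the nearest integer and clipped to
#' \[0, 255\]. Grayscale input is returned unchanged apart from rounding
#' and clipping.
#'
#' @param pixels A numeric H x W matrix (grayscale) or H x W x 3 array (RGB)
#'   with values on \[0, 255\].
#' @return Integer H x W matrix of intensities in \[0, 255\].
#' @export
#' @examples
#' to_gray(array(c(100, 200, 50), dim = c(1, 1, 3)))  # 153
to_gray <- function(pixels) {
  d <- dim(pixels)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("expected an H x W matrix or H x W x 3 array")
  if (length(d) == 3L) {
    if (d[3] != 3L) stop("3-D input must have exactly 3 channels")
    pixels <- matrix(0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] +
                       0.114 * pixels[, , 3L],
                     nrow = d[1L], ncol = d[2L])
  }
  g <- round(pixels)
  g[g < 0] <- 0L
  g[g > 255] <- 255L
  storage.mode(g) <- "integer"
  g
}

#' Global histogram equalization
#'
#' Each intensity `v` is remapped to `round(255 * cdf(v))`, where `cdf` is
#' the normalized cumulative histogram of the input. Equalization is global
#' (not adaptive); it spreads the gray levels of a low-contrast spread over
#' the full range before thresholding.
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @return Equalized integer matrix, same dimensions.
#' @export
#' @examples
#' equalize(matrix(c(0L, 85L, 170L, 255L), 2, 2))
equalize <- function(img) {
  stopifnot(is.matrix(img), length(img) >= 1L)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  lut <- as.integer(round(255 * cdf))
  out <- matrix(lut[as.integer(img) + 1L], nrow = nrow(img))
  out
}

#' Otsu's automatic threshold
#'
#' Returns the threshold `t` in \[0, 255\] maximizing the between-class
#' variance of the partition `{v <= t}` vs `{v > t}`. Ties are broken by
#' the smallest qualifying `t`.
#'
#' @param img Integer matrix of intensities in \[0, 255\] with at least two
#'   distinct values.
#' @return Integer threshold.
#' @export
#' @examples
#' otsu_threshold(matrix(c(10L, 10L, 200L, 200L), 2, 2))  # 10
otsu_threshold <- function(img) {
  v <- as.integer(img)
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("no separable classes: image has a single intensity value")
  n <- length(v)
  levels <- 0:255
  w0 <- cumsum(counts) / n                 # P(v <= t), t = 0..255
  s0 <- cumsum(counts * levels)            # sum of intensities <= t
  total <- s0[256L]
  mu0 <- ifelse(w0 > 0, s0 / (w0 * n), 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (total - s0) / (w1 * n), 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2       # between-class variance at t
  valid <- w0 > 0 & w1 > 0
  sigma_b[!valid] <- -Inf
  as.integer(which.max(sigma_b) - 1L)      # which.max takes the first max
}

#' Segment foreground objects from a grayscale spread
#'
#' Binarizes at the Otsu threshold, taking as foreground the side of the
#' threshold with the lower mean intensity (Giemsa-stained objects are dark
#' on a light background; the polarity test makes the pipeline robust to
#' inverted scans). Foreground is split into 8-connected components; those
#' smaller than `min_object_px` pixels are dropped as stain noise. Object
#' ids are assigned in raster order of each component's top-left
#' bounding-box corner.
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @param min_object_px Minimum component size kept, in pixels (default 20).
#' @return List of `segmented_object`s, each with fields `object_id`,
#'   `mask` (tight-cropped 0/1 matrix), `bbox_origin` (0-based `(row, col)`
#'   of the crop in the source), `pixel_count`, and `touches_border`.
#' @export
segment_objects <- function(img, min_object_px = 20L) {
  stopifnot(is.matrix(img), min_object_px >= 1L)
  t <- otsu_threshold(img)
  low <- img <= t
  mean_low <- mean(img[low])
  mean_high <- mean(img[!low])
  fg <- if (mean_low < mean_high) low else !low
  mask <- matrix(as.integer(fg), nrow = nrow(img))
  labels <- .cc_label(mask, 8L)
  n_lab <- max(labels)
  if (n_lab == 0L) return(list())

  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  sizes <- tabulate(lab, nbins = n_lab)
  r_min <- vapply(split(idx[, 1L], lab), min, 1L)
  r_max <- vapply(split(idx[, 1L], lab), max, 1L)
  c_min <- vapply(split(idx[, 2L], lab), min, 1L)
  c_max <- vapply(split(idx[, 2L], lab), max, 1L)

  keep <- which(sizes >= min_object_px)
  keep <- keep[order(r_min[keep], c_min[keep])]
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    sub <- labels[r_min[k]:r_max[k], c_min[k]:c_max[k], drop = FALSE]
    m <- matrix(as.integer(sub == k), nrow = nrow(sub))
    out[[i]] <- structure(
      list(object_id = i,
           mask = m,
           bbox_origin = c(row = unname(r_min[k]) - 1L,
                           col = unname(c_min[k]) - 1L),
           pixel_count = sizes[k],
           touches_border = r_min[k] == 1L || c_min[k] == 1L ||
             r_max[k] == nrow(img) || c_max[k] == ncol(img)),
      class = "segmented_object")
  }
  out
}

# Rotate a binary mask by `angle_deg` (counter-clockwise positive in the
# Cartesian frame, i.e. with the row axis pointing up). Nearest-neighbor
# sampling keeps the mask strictly binary. Returns an uncropped matrix
# covering the rotated extent.
.rotate_mask <- function(mask, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(mask)
  th <- angle_deg * pi / 180
  nr <- nrow(mask); nc <- ncol(mask)
  yc <- (nr + 1) / 2; xc <- (nc + 1) / 2
  # forward-rotate the corners to size the output canvas
  cx <- c(1, 1, nc, nc) - xc
  cy <- -(c(1, nr, 1, nr) - yc)
  fx <- cos(th) * cx - sin(th) * cy
  fy <- sin(th) * cx + cos(th) * cy
  nc_out <- ceiling(max(fx) - min(fx) - 1e-7) + 1L
  nr_out <- ceiling(max(fy) - min(fy) - 1e-7) + 1L
  yco <- (nr_out + 1) / 2; xco <- (nc_out + 1) / 2
  xo <- rep(seq_len(nc_out) - xco, each = nr_out)
  yo <- rep(-(seq_len(nr_out) - yco), times = nc_out)
  # inverse rotation maps output pixel centers back into the source
  xi <- cos(th) * xo + sin(th) * yo + xc
  yi <- -(-sin(th) * xo + cos(th) * yo) + yc
  ri <- as.integer(round(yi)); ci <- as.integer(round(xi))
  ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
  vals <- integer(nr_out * nc_out)
  vals[ok] <- mask[cbind(ri[ok], ci[ok])]
  matrix(vals, nrow = nr_out)
}

# Crop a 0/1 matrix to its tight bounding box; errors on an empty mask.
.tight_crop <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) stop("empty mask")
  mask[rows[1L]:rows[length(rows)], cols[1L]:cols[length(cols)],
       drop = FALSE]
}

# Principal-axis angle of a mask, measured from the vertical (degrees,
# counter-clockwise positive, normalized to (-90, 90]). Returns 0 when the
# two principal moments coincide within 1e-9 (no defined major axis).
.principal_angle_from_vertical <- function(mask) {
  pts <- which(mask == 1L, arr.ind = TRUE)
  x <- pts[, 2L]; y <- -pts[, 1L]
  mx <- mean(x); my <- mean(y)
  mxx <- mean(x * x) - mx * mx
  myy <- mean(y * y) - my * my
  mxy <- mean(x * y) - mx * my
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE)
  if (ev$values[1L] - ev$values[2L] <= 1e-9) return(0)
  v <- ev$vectors[, 1L]
  # v = R(a) %*% c(0, 1) => v = (-sin a, cos a), a CCW from the +y axis
  a <- atan2(-v[1L], v[2L]) * 180 / pi
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

#' Rotate a segmented object to vertical orientation
#'
#' The orientation of the mask's principal (major) axis is computed from
#' second-order central moments and the mask rotated so the major axis is
#' vertical, using nearest-neighbor interpolation so the mask stays binary.
#' The result is tight-cropped and its pixel count recomputed, keeping the
#' object area and its enclosing rectangle in the same (rotated) frame.
#'
#' @param obj A `segmented_object` (or any list with a 0/1 `mask` matrix and
#'   an `object_id`).
#' @return An `oriented_object` with fields `object_id`, `mask`,
#'   `rotation_deg` (counter-clockwise positive), and `pixel_count`.
#' @export
orient_vertical <- function(obj) {
  mask <- obj$mask
  if (sum(mask) == 0L) stop("empty mask")
  if (sum(mask) < 3L) stop("mask too small for moment computation")
  ang <- .principal_angle_from_vertical(mask)
  # rotating by -ang brings the major axis to vertical
  rot <- if (ang == 0) mask else .tight_crop(.rotate_mask(mask, -ang))
  structure(
    list(object_id = obj$object_id,
         mask = rot,
         rotation_deg = -ang,
         pixel_count = sum(rot)),
    class = "oriented_object")
}
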