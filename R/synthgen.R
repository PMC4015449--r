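#' Specification for a synthetic metaphase spread
#'
#' Describes one synthetic Giemsa-like spread: dark banded chromosome
#' bodies (straight and bent), fused overlapping clusters, and debris blobs
#' on a light background with additive Gaussian noise. The defaults emulate
#' a typical human metaphase at moderate magnification: ~37 free chromosome
#' bodies plus 3 clusters of 2-3 fused bodies approximates the 46-chromosome
#' complement, with a handful of stain debris. Geometric ranges are chosen
#' so each rendered object's intended class is recoverable from its mask
#' geometry alone (see the package vignette for the margin derivation):
#' bent bodies bend at least 45 degrees so their tight bounding rectangle
#' empties below the straight gate, while their widest row stays near the
#' body width (an elbow crosses each row once); cluster bodies cross at
#' 76-90 degrees so rows through the fused mask cut two bodies at once and
#' the widest row clearly exceeds the overlap gate.
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_straight,n_bent,n_overlap_clusters,n_debris Object counts; an
#'   overlap cluster of 2-3 fused bodies counts as one Class-3 component.
#'   Debris alternates small round blobs, thin shallow arcs, and large
#'   irregular blobs, covering the three residue branches of the rule tree.
#' @param chrom_width_px Chromosome body width (pixels, default 8).
#' @param chrom_len_range_px `(min, max)` body length (pixels).
#' @param bend_angle_range_deg `(min, max)` bend for Class-2 bodies.
#' @param band_contrast Transverse banding amplitude as a fraction of the
#'   object-background contrast, in \[0, 1\].
#' @param noise_sd Additive Gaussian pixel noise, intensity units.
#' @param seed Integer; fixes the entire rendered output bit-exactly.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(image_size = c(512L, 640L),
                       n_straight = 20L,
                       n_bent = 14L,
                       n_overlap_clusters = 3L,
                       n_debris = 6L,
                       chrom_width_px = 8,
                       chrom_len_range_px = c(36, 90),
                       bend_angle_range_deg = c(45, 90),
                       band_contrast = 0.35,
                       noise_sd = 8,
                       seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 64),
            n_straight >= 0L, n_bent >= 0L, n_overlap_clusters >= 0L,
            n_debris >= 0L, chrom_width_px >= 2,
            length(chrom_len_range_px) == 2L,
            chrom_len_range_px[1L] > chrom_width_px,
            diff(chrom_len_range_px) >= 0,
            length(bend_angle_range_deg) == 2L,
            bend_angle_range_deg[1L] > 0, diff(bend_angle_range_deg) >= 0,
            band_contrast >= 0, band_contrast <= 1, noise_sd >= 0,
            is.finite(seed))
  structure(list(image_size = as.integer(image_size),
                 n_straight = as.integer(n_straight),
                 n_bent = as.integer(n_bent),
                 n_overlap_clusters = as.integer(n_overlap_clusters),
                 n_debris = as.integer(n_debris),
                 chrom_width_px = chrom_width_px,
                 chrom_len_range_px = chrom_len_range_px,
                 bend_angle_range_deg = bend_angle_range_deg,
                 band_contrast = band_contrast,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Background and object base intensities of the renderer (8-bit scale).
.SYNTH_BG <- 200
.SYNTH_FG <- 60

# Distance from points (px, py) to segment a-b, plus the projection
# parameter t in [0, 1]. Vectorized over points.
.seg_dist <- function(px, py, a, b) {
  vx <- b[1L] - a[1L]; vy <- b[2L] - a[2L]
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - a[1L]) * vx + (py - a[2L]) * vy) / len2))
  dx <- px - (a[1L] + t * vx)
  dy <- py - (a[2L] + t * vy)
  list(dist = sqrt(dx * dx + dy * dy), t = t)
}

# Crop a gray/mask tile pair to the mask's tight bounding box.
.crop_tile <- function(gray, mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) stop("invalid geometry: empty rendered mask")
  rr <- rows[1L]:rows[length(rows)]; cc <- cols[1L]:cols[length(cols)]
  list(gray = gray[rr, cc, drop = FALSE], mask = mask[rr, cc, drop = FALSE])
}

#' Render one chromosome body
#'
#' Draws a dark elongated body of constant width along a straight or bent
#' medial path, with transverse sinusoidal banding. The body is the set of
#' pixels within `width_px / 2` of the path; a bend splits the path into
#' two equal arms whose directions differ by `bend_deg`. Rendering is fully
#' deterministic given its arguments.
#'
#' @param length_px Total path length (pixels); must exceed `width_px`.
#' @param width_px Body width (pixels, >= 2).
#' @param bend_deg Angle between the two arm directions (0 = straight).
#' @param band_contrast Banding amplitude fraction in \[0, 1\].
#' @param orientation_deg Direction of the body axis, degrees from
#'   vertical.
#' @return List with `gray` (intensity tile, `NA` background) and `mask`
#'   (0/1 matrix), tight-cropped.
#' @export
render_chromosome <- function(length_px, width_px, bend_deg = 0,
                              band_contrast = 0.35, orientation_deg = 0) {
  stopifnot(width_px >= 2, length_px > width_px,
            bend_deg >= 0, bend_deg < 180)
  half <- length_px / 2
  t1 <- (orientation_deg - bend_deg / 2) * pi / 180
  t2 <- (orientation_deg + bend_deg / 2) * pi / 180
  # path: end1 -> apex (origin) -> end2; turn at the apex equals bend_deg
  end1 <- c(-half * sin(t1), -half * cos(t1))
  apex <- c(0, 0)
  end2 <- c(half * sin(t2), half * cos(t2))
  pad <- width_px / 2 + 2
  xr <- range(end1[1L], apex[1L], end2[1L]) + c(-pad, pad)
  yr <- range(end1[2L], apex[2L], end2[2L]) + c(-pad, pad)
  xs <- seq(floor(xr[1L]), ceiling(xr[2L]))
  ys <- seq(floor(yr[1L]), ceiling(yr[2L]))
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  d1 <- .seg_dist(px, py, end1, apex)
  d2 <- .seg_dist(px, py, apex, end2)
  use1 <- d1$dist <= d2$dist
  dist <- ifelse(use1, d1$dist, d2$dist)
  s <- ifelse(use1, d1$t * half, half + d2$t * half)  # arclength position
  inside <- dist <= width_px / 2
  amp <- band_contrast * (.SYNTH_BG - .SYNTH_FG) * 0.5
  band_period <- 7  # px between band centers, Giemsa-like at this scale
  val <- round(.SYNTH_FG + amp * (0.5 + 0.5 * sin(2 * pi * s / band_period)))
  gray <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  mask <- matrix(0L, nrow = length(ys), ncol = length(xs))
  gray[cbind(py - ys[1L] + 1L, px - xs[1L] + 1L)[inside, , drop = FALSE]] <-
    val[inside]
  mask[cbind(py - ys[1L] + 1L, px - xs[1L] + 1L)[inside, , drop = FALSE]] <- 1L
  .crop_tile(gray, mask)
}

# Roughened ellipse blob (debris). Deterministic given arguments.
.render_blob <- function(d_major, d_minor, orientation_deg = 0,
                         roughness = 0, phase = 0) {
  a <- d_major / 2; b <- d_minor / 2
  pad <- ceiling(a * (1 + roughness) + 2)
  xs <- seq(-pad, pad); ys <- seq(-pad, pad)
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  th <- orientation_deg * pi / 180
  xr <- cos(th) * px + sin(th) * py
  yr <- -sin(th) * px + cos(th) * py
  rr <- sqrt((xr / a)^2 + (yr / b)^2)
  phi <- atan2(yr / b, xr / a)
  inside <- rr <= 1 + roughness * sin(3 * phi + phase)
  gray <- matrix(NA_real_, length(ys), length(xs))
  mask <- matrix(0L, length(ys), length(xs))
  ij <- cbind(py + pad + 1L, px + pad + 1L)
  gray[ij[inside, , drop = FALSE]] <- .SYNTH_FG + 10
  mask[ij[inside, , drop = FALSE]] <- 1L
  .crop_tile(gray, mask)
}

# Thin shallow arc (debris). Deterministic given arguments.
.render_arc <- function(radius, thickness, span_deg, orientation_deg = 0) {
  pad <- ceiling(radius + thickness + 2)
  xs <- seq(-pad, pad); ys <- seq(-pad, pad)
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  rr <- sqrt(px^2 + py^2)
  ang <- atan2(py, px) * 180 / pi
  dang <- ((ang - orientation_deg + 180) %% 360) - 180
  inside <- abs(rr - radius) <= thickness / 2 & abs(dang) <= span_deg / 2
  gray <- matrix(NA_real_, length(ys), length(xs))
  mask <- matrix(0L, length(ys), length(xs))
  ij <- cbind(py + pad + 1L, px + pad + 1L)
  gray[ij[inside, , drop = FALSE]] <- .SYNTH_FG + 10
  mask[ij[inside, , drop = FALSE]] <- 1L
  .crop_tile(gray, mask)
}

# Binary dilation by a Chebyshev radius (8-neighbor square element).
.dilate <- function(mask, r = 1L) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(r)) {
    m <- out
    out[-1L, ] <- pmax(out[-1L, ], m[-nr, ])
    out[-nr, ] <- pmax(out[-nr, ], m[-1L, ])
    out[, -1L] <- pmax(out[, -1L], out[, -nc])
    out[, -nc] <- pmax(out[, -nc], out[, -1L])
  }
  out
}

# Fuse 2-3 chromosome bodies crossing near a common point into one tile.
# Crossing angles are drawn from [76, 90] degrees so the fused mask's
# widest row is well above the overlap gate. Draws from the global RNG.
.render_cluster <- function(spec) {
  for (attempt in 1:50) {
    n_bodies <- sample(2:3, 1L)
    base <- runif(1, -90, 90)
    gaps <- cumsum(c(0, sample(c(-1, 1), n_bodies - 1L, replace = TRUE) *
                       runif(n_bodies - 1L, 76, 90)))
    tiles <- lapply(seq_len(n_bodies), function(i) {
      len <- runif(1, max(50, spec$chrom_len_range_px[1L]),
                   spec$chrom_len_range_px[2L])
      render_chromosome(len, spec$chrom_width_px, 0, spec$band_contrast,
                        orientation_deg = base + gaps[i])
    })
    h <- max(vapply(tiles, function(t) nrow(t$mask), 1L)) + 8L
    w <- max(vapply(tiles, function(t) ncol(t$mask), 1L)) + 8L
    gray <- matrix(NA_real_, h, w)
    mask <- matrix(0L, h, w)
    for (t in tiles) {
      th <- nrow(t$mask); tw <- ncol(t$mask)
      r0 <- floor((h - th) / 2) + sample(-3:3, 1L)
      c0 <- floor((w - tw) / 2) + sample(-3:3, 1L)
      rr <- r0 + seq_len(th); cc <- c0 + seq_len(tw)
      sel <- t$mask == 1L
      sub <- gray[rr, cc, drop = FALSE]
      sub[sel] <- pmin(sub[sel], t$gray[sel], na.rm = TRUE)
      gray[rr, cc] <- sub
      msub <- mask[rr, cc, drop = FALSE]
      msub[sel] <- 1L
      mask[rr, cc] <- msub
    }
    if (max(.cc_label(mask, 8L)) == 1L) return(.crop_tile(gray, mask))
  }
  stop("could not fuse cluster bodies into one component")
}

#' Render a synthetic metaphase spread with ground truth
#'
#' Places straight bodies (Class 1), bent bodies (Class 2), fused crossing
#' clusters (Class 3) and debris (Class 4) on a light background by
#' rejection sampling. Non-cluster components are kept at least two pixels
#' apart (no 8-connected contact), so at `noise_sd = 0` segmentation
#' recovers exactly one component per ground-truth record. Gaussian pixel
#' noise of sd `noise_sd` is added last. The full output is a
#' deterministic function of `spec` (including its `seed`).
#'
#' @param spec A [synth_spec()].
#' @return List with `image` (integer intensity matrix), `truth` (data
#'   frame: `object_id`, `true_class`, `centroid_row`, `centroid_col`,
#'   `row_min`, `col_min`, `row_max`, `col_max`; 1-based pixel
#'   coordinates), and `spec`.
#' @export
render_spread <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  canvas <- matrix(.SYNTH_BG, H, W)
  occ <- matrix(0L, H, W)
  truth <- list()

  place_tile <- function(tile, true_class) {
    m <- tile$mask
    th <- nrow(m); tw <- ncol(m)
    if (th + 4L > H || tw + 4L > W)
      stop("overcrowded spec: object larger than the canvas")
    # pad by 2 so a dilated-collision pass guarantees a >= 2 px gap
    pm <- matrix(0L, th + 4L, tw + 4L)
    pm[3:(th + 2L), 3:(tw + 2L)] <- m
    dil <- .dilate(pm, 2L)
    for (try in 1:1000) {
      r0 <- sample.int(H - th - 4L + 1L, 1L)
      c0 <- sample.int(W - tw - 4L + 1L, 1L)
      region <- occ[r0:(r0 + th + 3L), c0:(c0 + tw + 3L)]
      if (any(region & dil)) next
      rr <- (r0 + 2L):(r0 + th + 1L); cc <- (c0 + 2L):(c0 + tw + 1L)
      sel <- m == 1L
      sub <- canvas[rr, cc]
      sub[sel] <- tile$gray[sel]
      canvas[rr, cc] <<- sub
      osub <- occ[rr, cc]
      osub[sel] <- 1L
      occ[rr, cc] <<- osub
      pts <- which(sel, arr.ind = TRUE)
      truth[[length(truth) + 1L]] <<- data.frame(
        true_class = true_class,
        centroid_row = mean(pts[, 1L]) + rr[1L] - 1,
        centroid_col = mean(pts[, 2L]) + cc[1L] - 1,
        row_min = rr[1L], col_min = cc[1L],
        row_max = rr[1L] + th - 1L, col_max = cc[1L] + tw - 1L)
      return(invisible(NULL))
    }
    stop("overcrowded spec: placement failed after 1000 attempts")
  }

  lrange <- spec$chrom_len_range_px
  # big components first so rejection sampling converges
  for (i in seq_len(spec$n_overlap_clusters))
    place_tile(.render_cluster(spec), 3L)
  debris_kind <- rep(c("large", "small", "arc"),
                     length.out = spec$n_debris)
  for (kind in debris_kind[debris_kind == "large"]) {
    d <- runif(1, 18, 24)
    place_tile(.render_blob(d, 0.8 * d, runif(1, -90, 90),
                            roughness = 0.05, phase = runif(1, 0, 2 * pi)),
               4L)
  }
  for (i in seq_len(spec$n_straight)) {
    len <- runif(1, lrange[1L], lrange[2L])
    place_tile(render_chromosome(len, spec$chrom_width_px, 0,
                                 spec$band_contrast,
                                 orientation_deg = runif(1, -90, 90)), 1L)
  }
  for (i in seq_len(spec$n_bent)) {
    len <- runif(1, max(52, lrange[1L]), lrange[2L])
    bend <- runif(1, spec$bend_angle_range_deg[1L],
                  spec$bend_angle_range_deg[2L])
    place_tile(render_chromosome(len, spec$chrom_width_px, bend,
                                 spec$band_contrast,
                                 orientation_deg = runif(1, -90, 90)), 2L)
  }
  for (kind in debris_kind[debris_kind != "large"]) {
    if (kind == "small") {
      place_tile(.render_blob(6.5, 6.5, 0, roughness = 0.12,
                              phase = runif(1, 0, 2 * pi)), 4L)
    } else {
      place_tile(.render_arc(runif(1, 5.5, 7), 3, runif(1, 120, 160),
                             orientation_deg = runif(1, 0, 360)), 4L)
    }
  }

  if (spec$noise_sd > 0)
    canvas <- canvas + rnorm(length(canvas), 0, spec$noise_sd)
  img <- matrix(as.integer(pmin(pmax(round(canvas), 0), 255)), H, W)
  truth_df <- if (length(truth) == 0L) {
    data.frame(object_id = integer(0), true_class = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               row_min = integer(0), col_min = integer(0),
               row_max = integer(0), col_max = integer(0))
  } else {
    cbind(object_id = seq_along(truth), do.call(rbind, truth))
  }
  list(image = img, truth = truth_df, spec = spec)
}

#' Write a batch of synthetic spreads to disk
#'
#' Materializes `n_spreads` rendered spreads as PNG images with matching
#' ground-truth CSVs (`spread_001.png` / `spread_001_truth.csv`, ...).
#' Spread `i` uses seed `base_spec$seed + i - 1`.
#'
#' @param dir Output directory (created if needed).
#' @param n_spreads Number of spreads.
#' @param base_spec A [synth_spec()] serving as the template.
#' @return Data frame with `image` and `truth` file paths, invisibly.
#' @export
write_spread_batch <- function(dir, n_spreads = 10L,
                               base_spec = synth_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", n_spreads)
  for (i in seq_len(n_spreads)) {
    sp <- base_spec
    sp$seed <- base_spec$seed + i - 1L
    r <- render_spread(sp)
    img_path <- file.path(dir, sprintf("spread_%03d.png", i))
    truth_path <- file.path(dir, sprintf("spread_%03d_truth.csv", i))
    write_gray_png(r$image, img_path)
    write.csv(r$truth, truth_path, row.names = FALSE)
    out[[i]] <- data.frame(image = img_path, truth = truth_path)
  }
  invisible(do.call(rbind, out))
}

#' Score the pipeline against a rendered spread's ground truth
#'
#' Runs [classify_spread_image()] on a rendered spread and matches each
#' ground-truth component to the nearest predicted object by centroid
#' distance (greedy, one-to-one). Unmatched truth records get `NA`
#' predictions and count as errors in any accuracy tally.
#'
#' @param rendered Output of [render_spread()].
#' @param thresholds A [rule_thresholds()] object.
#' @param min_object_px Minimum component size kept (pixels).
#' @return Data frame with `object_id`, `true_class`, `pred_class`.
#' @export
evaluate_spread <- function(rendered, thresholds = rule_thresholds(),
                            min_object_px = 20L) {
  res <- classify_spread_image(rendered$image, thresholds, min_object_px)
  truth <- rendered$truth
  pred_class <- rep(NA_integer_, nrow(truth))
  if (length(res$objects) > 0L && nrow(truth) > 0L) {
    cent <- t(vapply(res$objects, function(o) {
      pts <- which(o$mask == 1L, arr.ind = TRUE)
      c(mean(pts[, 1L]) + o$bbox_origin[["row"]],
        mean(pts[, 2L]) + o$bbox_origin[["col"]])
    }, numeric(2)))
    d <- outer(truth$centroid_row, cent[, 1L], "-")^2 +
      outer(truth$centroid_col, cent[, 2L], "-")^2
    cls <- res$labels$class[match(vapply(res$objects, `[[`, 1L, "object_id"),
                                  res$labels$object_id)]
    for (k in seq_len(min(nrow(d), ncol(d)))) {
      ij <- arrayInd(which.min(d), dim(d))
      pred_class[ij[1L]] <- cls[ij[2L]]
      d[ij[1L], ] <- Inf
      d[, ij[2L]] <- Inf
    }
  }
  data.frame(object_id = truth$object_id, true_class = truth$true_class,
             pred_class = pred_class)
}
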