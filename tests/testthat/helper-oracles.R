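# Independent oracles and mask-construction helpers shared by the tests.
# These deliberately avoid the package's own code paths (except where a
# helper only builds input data).

# Exhaustive-search Otsu: try all 256 thresholds, recompute class means
# from scratch, keep the first (smallest) maximizer.
oracle_otsu <- function(img) {
  v <- as.vector(img)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    g1 <- v[v <= t]; g2 <- v[v > t]
    if (length(g1) == 0L || length(g2) == 0L) next
    sb <- (length(g1) * length(g2) / length(v)^2) *
      (mean(g1) - mean(g2))^2
    if (sb > best + 1e-12) { best <- sb; bt <- t }
  }
  bt
}

# Flat transcription of the four-class decision rule, scalar form.
oracle_classify <- function(ar, wr, hr, wm, t) {
  if (ar > t$area_gate) {
    if (wr >= t$wrect_lo && wr <= t$wrect_hi) return(1L)
    return(4L)
  }
  if (hr < t$hi_min) return(4L)
  if (wm > t$wmax_gate) return(3L)
  2L
}

# Vectorized flat transcription (independent coding: arithmetic on logical
# branch indicators rather than nested ifelse).
oracle_classify_vec <- function(ar, wr, hr, wm, t) {
  straight <- ar > t$area_gate
  in_band <- wr >= t$wrect_lo & wr <= t$wrect_hi
  short <- hr < t$hi_min
  wide <- wm > t$wmax_gate
  out <- integer(length(ar))
  out[straight & in_band] <- 1L
  out[straight & !in_band] <- 4L
  out[!straight & short] <- 4L
  out[!straight & !short & wide] <- 3L
  out[!straight & !short & !wide] <- 2L
  out
}

# Angle-sweep orientation oracle: rotate the foreground point cloud (no
# resampling) and find the angle maximizing bounding-box height/width.
oracle_vertical_angle <- function(mask) {
  pts <- which(mask == 1L, arr.ind = TRUE)
  x <- pts[, 2L]; y <- -pts[, 1L]
  ratio <- function(a) {
    th <- a * pi / 180
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    diff(range(yr)) / max(diff(range(xr)), 1e-9)
  }
  angles <- seq(-89.75, 90, by = 0.25)
  angles[which.max(vapply(angles, ratio, 1))]
}

# Direct kernel-sum KDE oracle (explicit loop over grid points).
oracle_kernel_sum <- function(values, grid, h) {
  vapply(grid, function(g) sum(dnorm((g - values) / h)) / (length(values) * h),
         1)
}

# Solid rectangle mask of len x wid drawn at `angle_deg` from vertical
# inside an amply sized canvas (membership test in rotated coordinates,
# independent of the package's rotation code).
draw_rect_mask <- function(len, wid, angle_deg) {
  n <- ceiling(len + wid) + 10L
  cen <- (n + 1) / 2
  th <- angle_deg * pi / 180
  r <- rep(seq_len(n), times = n); c <- rep(seq_len(n), each = n)
  x <- c - cen; y <- -(r - cen)
  along <- -sin(th) * x + cos(th) * y   # coordinate along the long axis
  perp <- cos(th) * x + sin(th) * y
  inside <- abs(along) <= len / 2 & abs(perp) <= wid / 2
  matrix(as.integer(inside), nrow = n)  # (r, c) grid is column-major
}

# One-row completed feature data frame with free ratio values.
feat_row <- function(area_ratio, Wrect_ratio = 1.2, Hi_ratio = 1,
                     Wmax_ratio = 1.2, object_id = 1L) {
  data.frame(object_id = object_id, A_o = 320, W_rect = 8, H_rect = 40,
             area_ratio = area_ratio, W_i = 8, W_max = 8,
             Wrect_ratio = Wrect_ratio, H_i = 40, Hi_ratio = Hi_ratio,
             Wmax_ratio = Wmax_ratio)
}

# Random completed feature frame spanning all rule branches.
random_features <- function(n) {
  data.frame(object_id = seq_len(n), A_o = 1, W_rect = 1, H_rect = 1,
             area_ratio = runif(n, 0.01, 1),
             W_i = 1, W_max = 1,
             Wrect_ratio = runif(n, 0.1, 3),
             H_i = 1,
             Hi_ratio = runif(n, 0.1, 3),
             Wmax_ratio = runif(n, 0.5, 4))
}

# Random Gaussian pair with a guaranteed crossing between the means (each
# density dominates at its own mean, so pdf_a - pdf_b changes sign there).
random_separable_fits <- function() {
  repeat {
    ma <- runif(1, -10, 10); mb <- ma + runif(1, 0.1, 8)
    sa <- runif(1, 0.1, 4); sb <- runif(1, 0.1, 4)
    if (dnorm(0, 0, sa) > dnorm(ma - mb, 0, sb) &&
        dnorm(0, 0, sb) > dnorm(mb - ma, 0, sa))
      return(list(a = list(mean = ma, sd = sa),
                  b = list(mean = mb, sd = sb)))
  }
}
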