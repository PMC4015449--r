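#' Gaussian-kernel density estimate on a grid
#'
#' Diagnostic companion to the Gaussian threshold fits: estimates the
#' empirical density of a labeled feature sample with a Gaussian kernel and
#' Silverman's rule-of-thumb bandwidth, evaluated at the supplied grid
#' points. Thresholds themselves come from the Gaussian fits, not the KDE.
#'
#' @param values Numeric sample (finite, non-degenerate).
#' @param grid Sorted numeric evaluation points.
#' @return Numeric vector of density values (same length as `grid`).
#' @export
kde <- function(values, grid) {
  stopifnot(length(values) >= 1L, all(is.finite(values)),
            length(grid) >= 1L, !is.unsorted(grid))
  if (length(unique(values)) == 1L)
    stop("zero-variance sample: density bandwidth undefined")
  h <- bw.nrd0(values)
  colMeans(dnorm(outer(values, grid, "-") / h)) / h
}

#' Fit a Gaussian to a labeled feature sample
#'
#' @param values Numeric sample, `n >= 2`, nonzero variance.
#' @return A `gaussian_fit` list: `mean`, `sd` (n-1 denominator), `n`.
#' @export
#' @examples
#' fit_gaussian(c(0, 2))  # mean 1, sd sqrt(2)
fit_gaussian <- function(values) {
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  s <- sd(values)
  if (s == 0) stop("degenerate sample: zero variance")
  structure(list(mean = mean(values), sd = s, n = length(values)),
            class = "gaussian_fit")
}

#' Intercept of two Gaussian probability density functions
#'
#' Solves `pdf_a(x) = pdf_b(x)` for the crossing point lying strictly
#' between the two means — the decision boundary used to separate two
#' feature classes. Equating log-densities gives a quadratic in `x`; with
#' equal standard deviations the unique crossing is the midpoint of the
#' means.
#'
#' When one class's density is much narrower than the other's and the
#' means are close, the narrow density can dominate the whole interval
#' between the means; both crossings then lie outside it and no single
#' cutoff separates the classes. This nested-classes degeneracy raises an
#' error rather than returning a meaningless boundary.
#'
#' @param a,b `gaussian_fit` objects (or lists with `mean` and `sd`);
#'   `a$mean != b$mean`.
#' @return The crossing point (numeric scalar).
#' @export
#' @examples
#' gaussian_intercept(list(mean = 0, sd = 1), list(mean = 2, sd = 1))  # 1
gaussian_intercept <- function(a, b) {
  if (a$mean == b$mean) stop("means are equal: no decision boundary")
  stopifnot(a$sd > 0, b$sd > 0)
  lo <- min(a$mean, b$mean); hi <- max(a$mean, b$mean)
  if (a$sd == b$sd) return((a$mean + b$mean) / 2)
  al <- 1 / (2 * a$sd^2); be <- 1 / (2 * b$sd^2)
  # -al (x-ma)^2 - log sa = -be (x-mb)^2 - log sb
  A <- be - al
  B <- 2 * (al * a$mean - be * b$mean)
  C <- be * b$mean^2 - al * a$mean^2 + log(b$sd / a$sd)
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("no real crossing (cannot occur for distinct means)")
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  inside <- roots > lo & roots < hi
  if (!any(inside))
    stop("no crossing between the means: the narrower class density ",
         "dominates the whole interval (nested classes)")
  roots[inside][1L]
}

#' Calibrate a decision threshold from two labeled samples
#'
#' Reproduces the statistical procedure behind the shipped rule constants:
#' fit a Gaussian to the feature values of each class and take the
#' intercept of the two fitted densities as the threshold. The result also
#' carries a plot-ready grid (kernel density estimates and both Gaussian
#' pdfs) for visual inspection of how well the Gaussian model matches the
#' empirical densities.
#'
#' @param class_a,class_b Numeric feature samples for the two classes.
#' @param grid_n Number of grid points for the diagnostic densities.
#' @return A `calibration` list: `threshold`, `fit_a`, `fit_b`, `n_a`,
#'   `n_b`, and `grid` (data frame with `x`, `kde_a`, `kde_b`, `pdf_a`,
#'   `pdf_b`).
#' @export
calibrate_threshold <- function(class_a, class_b, grid_n = 512L) {
  fa <- fit_gaussian(class_a)
  fb <- fit_gaussian(class_b)
  thr <- gaussian_intercept(fa, fb)
  lo <- min(class_a, class_b) - 3 * max(fa$sd, fb$sd)
  hi <- max(class_a, class_b) + 3 * max(fa$sd, fb$sd)
  x <- seq(lo, hi, length.out = grid_n)
  grid <- data.frame(x = x,
                     kde_a = kde(class_a, x),
                     kde_b = kde(class_b, x),
                     pdf_a = dnorm(x, fa$mean, fa$sd),
                     pdf_b = dnorm(x, fb$mean, fb$sd))
  structure(list(threshold = thr, fit_a = fa, fit_b = fb,
                 n_a = fa$n, n_b = fb$n, grid = grid),
            class = "calibration")
}

#' One-sample quantile threshold
#'
#' Alternative calibration mode for a single labeled population: the
#' threshold is placed `z` standard deviations from the fitted mean. Useful
#' when only one class was sampled and the boundary is a tail cutoff rather
#' than a two-class intercept.
#'
#' @param fit A `gaussian_fit`.
#' @param z Number of standard deviations from the mean (default 2).
#' @param side `"upper"` (mean + z sd) or `"lower"` (mean - z sd).
#' @return Numeric threshold.
#' @export
quantile_threshold <- function(fit, z = 2, side = c("upper", "lower")) {
  side <- match.arg(side)
  stopifnot(z > 0, fit$sd > 0)
  if (side == "upper") fit$mean + z * fit$sd else fit$mean - z * fit$sd
}

#' Read labeled feature samples from CSV
#'
#' Expects columns `value` (numeric) and `label` (class tag).
#'
#' @param path CSV path.
#' @return Named list of numeric vectors, one per label.
#' @export
read_labeled_samples <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("value", "label") %in% names(d)))
    stop("labeled-sample CSV needs columns 'value' and 'label'")
  split(as.numeric(d$value), d$label)
}

#' Write a calibration report as JSON
#'
#' @param cal A `calibration` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(
    list(threshold = cal$threshold,
         fit_a = cal$fit_a[c("mean", "sd", "n")],
         fit_b = cal$fit_b[c("mean", "sd", "n")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a calibration: empirical and fitted densities
#'
#' Draws the kernel density estimates of both classes, the two fitted
#' Gaussian curves, and the threshold at their intercept.
#'
#' @param x A `calibration` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.calibration <- function(x, ...) {
  g <- x$grid
  graphics::matplot(g$x, cbind(g$kde_a, g$kde_b, g$pdf_a, g$pdf_b),
                    type = "l", lty = c(1, 1, 2, 2),
                    col = c("grey40", "grey70", "firebrick", "steelblue"),
                    xlab = "feature value", ylab = "density", ...)
  graphics::abline(v = x$threshold, col = "black", lty = 3)
  graphics::legend("topright",
                   legend = c("kde A", "kde B", "gaussian A", "gaussian B"),
                   lty = c(1, 1, 2, 2),
                   col = c("grey40", "grey70", "firebrick", "steelblue"),
                   bty = "n")
  invisible(x)
}
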