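#' Gray-level discretization rule
#'
#' @param mode \code{"fixed_bin_count"} (equal-width bins spanning the
#'   in-mask intensity range) or \code{"fixed_bin_width"}.
#' @param bins number of bins (>= 2) for \code{fixed_bin_count}.
#' @param width bin width (> 0) for \code{fixed_bin_width}.
#' @return a list of class \code{discretizationRule}.
#' @export
discretizationRule <- function(mode = c("fixed_bin_count", "fixed_bin_width"),
                               bins = 32, width = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_count") stopifnot(bins >= 2)
  if (mode == "fixed_bin_width") stopifnot(!is.null(width), width > 0)
  structure(list(mode = mode, bins = as.integer(bins), width = width),
            class = "discretizationRule")
}

#' Discretize in-mask intensities to consecutive gray levels
#'
#' Fixed-bin-count mode spans \code{[min, max]} of the in-mask intensities
#' with equal-width bins; a constant region maps to level 1. Fixed-bin-width
#' mode anchors bins at the in-mask minimum. Output levels are consecutive
#' integers starting at 1; pixels outside the mask are 0.
#'
#' @param image numeric matrix.
#' @param mask logical matrix.
#' @param rule a \code{\link{discretizationRule}}.
#' @return integer matrix of gray levels (0 outside the mask) with attribute
#'   \code{nGray}.
#' @export
discretize <- function(image, mask, rule = discretizationRule()) {
  stopifnot(any(mask))
  x <- image[mask]
  lo <- min(x)
  if (rule$mode == "fixed_bin_count") {
    rng <- max(x) - lo
    if (rng <= 0) {
      lev <- rep(1L, length(x))
      ng <- 1L
    } else {
      w <- rng / rule$bins
      lev <- pmin.int(floor((x - lo) / w) + 1L, rule$bins)
      ng <- rule$bins
    }
  } else {
    lev <- floor((x - lo) / rule$width) + 1L
    ng <- max(lev)
  }
  out <- matrix(0L, nrow(image), ncol(image))
  out[mask] <- as.integer(lev)
  attr(out, "nGray") <- as.integer(ng)
  out
}

#' First-order (histogram) features
#'
#' IBSI-style intensity statistics over the in-mask pixels. Entropy and
#' uniformity are computed on the discretized gray-level histogram; all other
#' statistics on the raw intensities. Moments are population moments;
#' kurtosis is excess kurtosis. Degenerate single-valued regions get
#' skewness and kurtosis 0 by convention.
#'
#' @param image numeric matrix.
#' @param mask logical matrix.
#' @param levels optional pre-discretized level matrix from
#'   \code{\link{discretize}} (recomputed with \code{rule} if missing).
#' @param rule \code{\link{discretizationRule}} for the histogram features.
#' @return named numeric vector (16 features).
#' @export
firstOrderFeatures <- function(image, mask, levels = NULL,
                               rule = discretizationRule()) {
  x <- image[mask]
  n <- length(x)
  if (is.null(levels)) levels <- discretize(image, mask, rule)
  p <- tabulate(levels[mask])
  p <- p[p > 0] / n
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  xs <- sort(x)
  # linear-interpolation (type 7) quantiles on the single sorted copy
  q7 <- function(pr) {
    h <- (n - 1) * pr + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[pmin(lo + 1, n)] - xs[lo])
  }
  qs <- q7(c(0.10, 0.25, 0.5, 0.75, 0.90))
  c(Mean = mu,
    Median = qs[3],
    Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    Uniformity = sum(p^2),
    Entropy = -sum(p * log2(p)),
    Energy = sum(x^2),
    Minimum = xs[1],
    Maximum = xs[n],
    Range = xs[n] - xs[1],
    InterquartileRange = qs[4] - qs[2],
    MeanAbsoluteDeviation = mean(abs(d)),
    RootMeanSquared = sqrt(mean(x^2)),
    P10 = qs[1],
    P90 = qs[5])
}

# Second central moments of the mask pixel coordinates (mm). Returns
# eigenvalues (descending) and the centroid.
maskMoments <- function(mask, spacing) {
  hit <- which(mask, arr.ind = TRUE)
  xy <- cbind(hit[, 1] * spacing[1], hit[, 2] * spacing[2])
  ctr <- colMeans(xy)
  d <- sweep(xy, 2, ctr)
  S <- crossprod(d) / nrow(d)
  list(lambda = sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE),
       centroid = ctr)
}

# Polygonal boundary length (mm) of a binary mask: the 0.5 iso-contour of
# the lightly smoothed indicator, which tracks the boundary with sub-pixel
# accuracy and avoids the staircase overestimate of pixel-edge counting.
maskPerimeter <- function(mask, spacing) {
  n <- nrow(mask); m <- ncol(mask)
  z <- matrix(0, n + 2, m + 2)
  z[2:(n + 1), 2:(m + 1)] <- as.numeric(mask)
  z <- gaussianBlur(z, 0.7)
  cl <- contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                     z = z, levels = 0.5)
  if (!length(cl)) return(0)
  per <- 0
  for (seg in cl) {
    dx <- diff(seg$x) * spacing[1]
    dy <- diff(seg$y) * spacing[2]
    per <- per + sum(sqrt(dx^2 + dy^2))
  }
  per
}

# Maximum diameter (mm): largest pairwise distance between boundary pixel
# centers, computed on the convex hull for speed.
maxDiameter <- function(mask, spacing) {
  hit <- which(mask, arr.ind = TRUE)
  if (nrow(hit) == 1) return(0)
  xy <- cbind(hit[, 1] * spacing[1], hit[, 2] * spacing[2])
  h <- grDevices::chull(xy)
  xy <- xy[h, , drop = FALSE]
  sqrt(max(as.vector(stats::dist(xy))^2))
}

#' 2D shape features
#'
#' Geometry of a single-connected-component mask: surface (area), polygonal
#' perimeter, perimeter-to-surface ratio, sphericity
#' \eqn{2\sqrt{\pi A}/P}, maximum diameter, major/minor axis lengths (four
#' times the square root of the second central moments' eigenvalues) and
#' elongation \eqn{\sqrt{\lambda_{minor}/\lambda_{major}}}.
#'
#' @param mask logical matrix (single connected component).
#' @param spacing numeric(2), mm.
#' @return named numeric vector (8 features).
#' @export
shapeFeatures2D <- function(mask, spacing = c(1, 1)) {
  if (!any(mask)) stop("empty mask")
  area <- sum(mask) * spacing[1] * spacing[2]
  per <- maskPerimeter(mask, spacing)
  mom <- maskMoments(mask, spacing)
  lam <- pmax(mom$lambda, 0)
  c(PixelSurface = area,
    Perimeter = per,
    PerimeterSurfaceRatio = per / area,
    Sphericity = if (per > 0) 2 * sqrt(pi * area) / per else 1,
    MaximumDiameter = maxDiameter(mask, spacing),
    MajorAxisLength = 4 * sqrt(lam[1]),
    MinorAxisLength = 4 * sqrt(lam[2]),
    Elongation = if (lam[1] > 0) sqrt(lam[2] / lam[1]) else 1)
}
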