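# Gray-level matrix feature families. All operate on a level matrix from
# discretize() (0 outside the mask, 1..nGray inside). Directional families
# (GLCM, GLRLM) use the four 2D directions at distance 1 and average the
# per-direction features; GLSZM (8-connected zones) and GLDM (Chebyshev
# distance-1 neighbourhood) are intrinsically direction-free.

.directions2d <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))


.glcmFeatureNames <- c("JointEnergy", "JointEntropy", "Contrast",
                       "Dissimilarity", "InverseDifferenceMoment",
                       "InverseDifference", "Correlation", "ClusterShade",
                       "ClusterProminence")

#' Gray-level co-occurrence features
#'
#' Symmetric GLCMs at distance 1 are built for the four 2D directions,
#' normalized, summarised per direction and averaged. On a constant region
#' the correlation is defined as 1 by convention.
#'
#' @param levels integer level matrix from \code{\link{discretize}}.
#' @return named numeric vector (9 features, direction-averaged).
#' @export
glcmFeatures <- function(levels) {
  ng <- attr(levels, "nGray")
  acc <- numeric(9)
  used <- 0L
  for (d in .directions2d) {
    P <- .cppGlcm(levels, ng, d[1], d[2])
    if (sum(P) == 0) next
    acc <- acc + .cppGlcmFeatures(P)
    used <- used + 1L
  }
  if (used == 0L) stop("mask has no pixel pairs in any direction")
  setNames(acc / used, .glcmFeatureNames)
}

# emphasis features depend only on the row/column marginals, so the full
# p/i^2-style matrices are never materialised
glrlmFeaturesFromMatrix <- function(R, nPixels) {
  nr <- sum(R)
  gi <- rowSums(R) / nr
  rj <- colSums(R) / nr
  iv <- seq_along(gi)
  jv <- seq_along(rj)
  pp <- R[R > 0] / nr
  c(ShortRunEmphasis = sum(rj / jv^2),
    LongRunEmphasis = sum(rj * jv^2),
    GrayLevelNonUniformity = sum(gi^2) * nr,
    GrayLevelNonUniformityNormalized = sum(gi^2),
    RunLengthNonUniformity = sum(rj^2) * nr,
    RunLengthNonUniformityNormalized = sum(rj^2),
    RunPercentage = nr / nPixels,
    LowGrayLevelRunEmphasis = sum(gi / iv^2),
    HighGrayLevelRunEmphasis = sum(gi * iv^2),
    RunEntropy = -sum(pp * log2(pp)))
}

#' Gray-level run-length features
#'
#' Runs of identical gray level along each of the four 2D directions;
#' per-direction features averaged.
#'
#' @param levels integer level matrix from \code{\link{discretize}}.
#' @return named numeric vector (10 features, direction-averaged).
#' @export
glrlmFeatures <- function(levels) {
  ng <- attr(levels, "nGray")
  np <- sum(levels > 0)
  per <- lapply(.directions2d, function(d) {
    R <- .cppGlrlm(levels, ng, d[1], d[2])
    glrlmFeaturesFromMatrix(R, np)
  })
  Reduce(`+`, per) / length(per)
}

#' Gray-level size-zone features
#'
#' Zones are 8-connected regions of identical gray level.
#'
#' @param levels integer level matrix from \code{\link{discretize}}.
#' @return named numeric vector (10 features).
#' @export
glszmFeatures <- function(levels) {
  ng <- attr(levels, "nGray")
  np <- sum(levels > 0)
  Z <- .cppGlszm(levels, ng)
  nz <- sum(Z)
  gi <- rowSums(Z) / nz
  zs <- colSums(Z) / nz
  iv <- seq_along(gi)
  sv <- seq_along(zs)
  pp <- Z[Z > 0] / nz
  c(SmallAreaEmphasis = sum(zs / sv^2),
    LargeAreaEmphasis = sum(zs * sv^2),
    GrayLevelNonUniformity = sum(gi^2) * nz,
    GrayLevelNonUniformityNormalized = sum(gi^2),
    SizeZoneNonUniformity = sum(zs^2) * nz,
    SizeZoneNonUniformityNormalized = sum(zs^2),
    ZonePercentage = nz / np,
    ZoneEntropy = -sum(pp * log2(pp)),
    LowGrayLevelZoneEmphasis = sum(gi / iv^2),
    HighGrayLevelZoneEmphasis = sum(gi * iv^2))
}

#' Gray-level dependence features
#'
#' For every in-mask pixel the dependence is one plus the number of in-mask
#' Chebyshev distance-1 neighbours whose gray level differs by at most
#' \code{alpha} (default 0, i.e. equal levels); the offset keeps dependence
#' indices >= 1 so the small-dependence emphasis is defined.
#'
#' @param levels integer level matrix from \code{\link{discretize}}.
#' @param alpha dependence tolerance on gray-level difference.
#' @return named numeric vector (9 features).
#' @export
gldmFeatures <- function(levels, alpha = 0L) {
  ng <- attr(levels, "nGray")
  # .cppGldm column c counts pixels with c-1 dependent neighbours, so column
  # index c equals the dependence j = neighbours + 1 directly
  D <- .cppGldm(levels, ng, as.integer(alpha))
  nd <- sum(D)
  gi <- rowSums(D) / nd
  dj <- colSums(D) / nd
  iv <- seq_along(gi)
  jv <- seq_along(dj)
  muj <- sum(jv * dj)
  pp <- D[D > 0] / nd
  c(SmallDependenceEmphasis = sum(dj / jv^2),
    LargeDependenceEmphasis = sum(dj * jv^2),
    GrayLevelNonUniformity = sum(gi^2) * nd,
    DependenceNonUniformity = sum(dj^2) * nd,
    DependenceNonUniformityNormalized = sum(dj^2),
    DependenceEntropy = -sum(pp * log2(pp)),
    DependenceVariance = sum((jv - muj)^2 * dj),
    LowGrayLevelEmphasis = sum(gi / iv^2),
    HighGrayLevelEmphasis = sum(gi * iv^2))
}
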