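# Internal numerical helpers shared across modules.

# Derive a reproducible 32-bit stage seed from a master seed. `stage` is a
# short string, `index` an optional counter (lesion number, variant number...).
deriveSeed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.double(master) %% 50021) * 40013 + h * 1009 + as.double(index) * 7919
  as.integer(s %% 2147483562) + 1L
}

# Separable Gaussian blur with edge renormalisation (matrix-band product).
# sigma is in pixels; sigma <= 0 returns the input unchanged. Band matrices
# are cached per (size, sigma).
.blurCache <- new.env(parent = emptyenv())
blurBand <- function(n, s) {
  key <- paste0(n, "_", signif(s, 10))
  B <- .blurCache[[key]]
  if (is.null(B)) {
    idx <- seq_len(n)
    B <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    B <- B / rowSums(B)
    .blurCache[[key]] <- B
  }
  B
}

gaussianBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  blurBand(nrow(mat), sigma) %*% mat %*% t(blurBand(ncol(mat), sigma))
}

# Spatially correlated Gaussian random field, standardized to zero mean and
# unit SD. correlation length given in pixels.
correlatedField <- function(nrow, ncol, correlationPx) {
  f <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (correlationPx > 0) f <- gaussianBlur(f, correlationPx)
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

# Signed distance (pixels) to the mask boundary: positive inside, negative
# outside, +/-0.5 at the pixels adjacent to the boundary.
signedDistance <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  din <- sqrt(.cppEdtSq(m))
  dout <- sqrt(.cppEdtSq(1L - m))
  ifelse(mask, din - 0.5, -(dout - 0.5))
}

# Largest connected component of a binary mask.
largestComponent <- function(mask, connectivity = 4L) {
  lab <- .cppLabel(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                   connectivity)
  if (max(lab) <= 1L) return(mask & (lab > 0L))
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Fill interior holes: background components not touching the image border
# become foreground.
fillHoles <- function(mask) {
  bg <- .cppLabel(matrix(as.integer(!mask), nrow(mask), ncol(mask)), 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# Largest 4-connected component with holes filled, in one C++ pass.
cleanMask <- function(mask) {
  .cppCleanMask(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

nComponents <- function(mask, connectivity = 4L) {
  max(.cppLabel(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                connectivity))
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical matrices of identical dimension.
#' @return \code{2|a \&\& b| / (|a| + |b|)}.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Image gradient magnitude by central differences (units: intensity / pixel).
gradientMagnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  sqrt((gx / 2)^2 + (gy / 2)^2)
}

significanceStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
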