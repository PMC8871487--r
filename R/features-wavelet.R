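# Single-level undecimated 2D wavelet decomposition with Coiflet-1 filters.
# Undecimated sub-bands are natively frame-sized, so the original mask can
# be applied to each band without any resampling.

# Coiflet-1 decomposition low-pass, rescaled so the low-pass sums to 1
# (keeps the LL band on the intensity scale of the input).
.coif1Lo <- c(-0.01565572813546454, -0.0727326195128539,
              0.38486484686420286, 0.8525720202122554,
              0.3378976624578092, -0.0727326195128539) / sqrt(2)
# Quadrature mirror high-pass: g[k] = (-1)^k h[L-1-k]
.coif1Hi <- rev(.coif1Lo) * c(1, -1, 1, -1, 1, -1)

.bandCache <- new.env(parent = emptyenv())

# n x n operator applying a filter along one dimension with half-sample
# symmetric boundary extension; cached per (n, filter).
waveletOperator <- function(n, filt, tag) {
  key <- paste0(tag, "_", n)
  if (!is.null(.bandCache[[key]])) return(.bandCache[[key]])
  L <- length(filt)
  off <- L %/% 2       # filter centered on the output sample
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(L)) {
      j <- i + k - off
      while (j < 1 || j > n) {
        if (j < 1) j <- 1 - j
        if (j > n) j <- 2 * n + 1 - j
      }
      W[i, j] <- W[i, j] + filt[k]
    }
  }
  .bandCache[[key]] <- W
  W
}

#' Single-level undecimated wavelet decomposition
#'
#' Decomposes a 2D frame into the four sub-bands LL, LH, HL, HH using
#' Coiflet-1 analysis filters with symmetric boundary extension. The first
#' letter is the filter applied along rows (vertical axis), the second along
#' columns (horizontal axis); LH therefore responds to intensity changes
#' along the horizontal direction, HL to changes along the vertical
#' direction. Sub-bands have the same size as the input.
#'
#' @param image numeric matrix, at least 8 x 8.
#' @return named list of four matrices: LL, LH, HL, HH.
#' @export
waveletDecompose <- function(image) {
  if (nrow(image) < 8 || ncol(image) < 8)
    stop("frame smaller than 8 x 8: wavelet filtering skipped")
  Lr <- waveletOperator(nrow(image), .coif1Lo, "lo")
  Hr <- waveletOperator(nrow(image), .coif1Hi, "hi")
  Lc <- waveletOperator(ncol(image), .coif1Lo, "lo")
  Hc <- waveletOperator(ncol(image), .coif1Hi, "hi")
  list(LL = Lr %*% image %*% t(Lc),
       LH = Lr %*% image %*% t(Hc),
       HL = Hr %*% image %*% t(Lc),
       HH = Hr %*% image %*% t(Hc))
}
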