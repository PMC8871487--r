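test_that("discretization maps intensities to consecutive levels from 1", {
  img <- matrix(0, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  lev <- discretize(img, mask, discretizationRule(bins = 32))
  expect_true(all(lev[mask] == 1))               # constant region

  img2 <- matrix(0:255, 16, 16)
  lev2 <- discretize(img2, matrix(TRUE, 16, 16),
                     discretizationRule("fixed_bin_width", width = 64))
  expect_setequal(unique(as.vector(lev2)), 1:4)

  set.seed(1)
  img3 <- matrix(rnorm(64), 8, 8)
  mask3 <- matrix(runif(64) < 0.8, 8, 8); mask3[1, 1] <- TRUE
  lev3 <- discretize(img3, mask3, discretizationRule(bins = 5))
  x <- img3[mask3]
  w <- (max(x) - min(x)) / 5
  expected <- pmin(floor((x - min(x)) / w) + 1, 5)
  expect_equal(lev3[mask3], as.integer(expected))
})

test_that("first-order features match hand arithmetic and conventions", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  f <- firstOrderFeatures(img, mask)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Median"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Energy"]), 30)

  const <- firstOrderFeatures(matrix(7, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(unname(const["Uniformity"]), 1)
  expect_equal(unname(const["Entropy"]), 0)
  expect_equal(unname(const["Skewness"]), 0)   # degenerate convention
  expect_equal(unname(const["Kurtosis"]), 0)

  set.seed(3)
  x <- rnorm(1000)
  img <- matrix(x, 40, 25)
  f <- firstOrderFeatures(img, matrix(TRUE, 40, 25))
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(f["Skewness"]), mean((x - mean(x))^3) / m2^1.5)
  expect_lt(abs(f["Skewness"]), 0.25)
  expect_lt(abs(f["Kurtosis"]), 0.5)
  expect_equal(unname(f["P90"]), unname(quantile(x, 0.9)))
})

test_that("shape features are exact on canonical geometries", {
  disk <- diskCase(radius = 20, imageSize = 64, sigma = 0)
  sh <- shapeFeatures2D(disk@manualMasks[[1]])
  expect_gt(sh[["Sphericity"]], 0.95)
  expect_lt(sh[["Sphericity"]], 1.02)

  ell <- makePhantom(phantomSpec(imageSize = 96, axes = c(16, 8),
                                 irregularity = 0, boundarySigma = 0))
  msk <- ell@manualMasks[[1]]
  she <- shapeFeatures2D(msk)
  # sqrt(lambda_minor / lambda_major) = b/a = 1/2 for a 2:1 ellipse;
  # cross-checked against an independent eigen decomposition of the pixel
  # coordinate covariance
  expect_lt(abs(she[["Elongation"]] - 0.5), 0.05)
  ev <- eigen(cov(which(msk, arr.ind = TRUE) * 1.0))$values
  expect_equal(she[["Elongation"]], sqrt(min(ev) / max(ev)),
               tolerance = 0.01)

  sq <- matrix(FALSE, 16, 16)
  sq[4:13, 4:13] <- TRUE
  shs <- shapeFeatures2D(sq, c(1, 1))
  expect_equal(shs[["PixelSurface"]], 100)
  expect_equal(shs[["MaximumDiameter"]], sqrt(2) * 9)
  expect_error(shapeFeatures2D(matrix(FALSE, 3, 3)), "empty")
})

test_that("GLCM counts and features match pair enumeration by hand", {
  lev <- matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  attr(lev, "nGray") <- 2L
  # horizontal offset (0,1): rows (1,1) and (2,2) -> symmetric counts
  P <- radstab:::.cppGlcm(lev, 2L, 0L, 1L)
  expect_equal(P, matrix(c(2, 0, 0, 2), 2, 2))
  # vertical offset (1,0): pairs (1,2) twice
  P2 <- radstab:::.cppGlcm(lev, 2L, 1L, 0L)
  expect_equal(P2, matrix(c(0, 2, 2, 0), 2, 2))

  chk <- matrix(rep(c(1L, 2L), 13)[1:25], 5, 5)   # checkerboard
  attr(chk, "nGray") <- 2L
  P0 <- radstab:::.cppGlcm(chk, 2L, 0L, 1L)
  expect_equal(oracleGlcmFeatures(P0)[["JointEnergy"]], 0.5)
  expect_equal(oracleGlcmFeatures(P0)[["Contrast"]], 1)

  const <- matrix(1L, 3, 3)
  attr(const, "nGray") <- 1L
  f <- glcmFeatures(const)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["JointEntropy"]], 0)
  expect_equal(f[["Correlation"]], 1)             # degenerate convention
})

test_that("GLRLM counts match run enumeration on a known row", {
  lev <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  attr(lev, "nGray") <- 2L
  R <- radstab:::.cppGlrlm(lev, 2L, 0L, 1L)
  expect_equal(R[1, 2], 1)                        # one run of 1s, length 2
  expect_equal(R[2, 2], 1)
  expect_equal(sum(R), 2)
  f <- radstab:::glrlmFeaturesFromMatrix(R, 4)
  expect_equal(f[["RunLengthNonUniformity"]],
               oracleGlrlmFeatures(R, 4)[["RunLengthNonUniformity"]])
})

test_that("constant regions give a single zone and unit non-uniformity", {
  lev <- matrix(1L, 4, 4)
  attr(lev, "nGray") <- 1L
  f <- glszmFeatures(lev)
  expect_equal(f[["SizeZoneNonUniformityNormalized"]], 1)
  expect_equal(f[["ZonePercentage"]], 1 / 16)
})

test_that("all four texture families equal their enumeration oracles on
           random images", {
  set.seed(99)
  for (i in 1:40) {
    lev <- randomLevels(8, 8, ng = sample(2:5, 1))
    ng <- attr(lev, "nGray")
    np <- sum(lev > 0)
    dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

    for (d in dirs) {
      P <- radstab:::.cppGlcm(lev, ng, d[1], d[2])
      expect_equal(P, oracleGlcmCounts(lev, ng, d[1], d[2]))
      R <- radstab:::.cppGlrlm(lev, ng, d[1], d[2])
      O <- oracleGlrlmCounts(lev, ng, d[1], d[2])
      expect_equal(R[, seq_len(ncol(O)), drop = FALSE], O)
      expect_true(all(R[, -seq_len(ncol(O))] == 0))
    }
    glcmPer <- lapply(dirs, function(d) {
      P <- oracleGlcmCounts(lev, ng, d[1], d[2])
      if (sum(P) == 0) NULL else oracleGlcmFeatures(P)
    })
    glcmPer <- glcmPer[!vapply(glcmPer, is.null, logical(1))]
    expect_equal(glcmFeatures(lev),
                 Reduce(`+`, glcmPer) / length(glcmPer),
                 tolerance = 1e-12)

    glrPer <- lapply(dirs, function(d)
      oracleGlrlmFeatures(oracleGlrlmCounts(lev, ng, d[1], d[2]), np))
    expect_equal(glrlmFeatures(lev), Reduce(`+`, glrPer) / 4,
                 tolerance = 1e-12)

    Zo <- oracleGlszmCounts(lev, ng)
    Z <- radstab:::.cppGlszm(lev, ng)
    expect_equal(sum(Z), sum(Zo))
    expect_equal(glszmFeatures(lev), oracleGlszmFeatures(Zo, np),
                 tolerance = 1e-12)

    Do <- oracleGldmCounts(lev, ng, 0)
    expect_equal(radstab:::.cppGldm(lev, ng, 0L), Do)
    expect_equal(gldmFeatures(lev), oracleGldmFeatures(Do),
                 tolerance = 1e-12)
  }
})

test_that("direction-averaged features are invariant to 90-degree rotation
           and count-based discretization ignores intensity shifts", {
  set.seed(5)
  img <- matrix(rnorm(100), 10, 10)
  mask <- matrix(runif(100) < 0.9, 10, 10); mask[5, 5] <- TRUE
  rule <- discretizationRule(bins = 8)
  lev <- discretize(img, mask, rule)
  levR <- discretize(t(img)[ncol(img):1, ], t(mask)[ncol(mask):1, ], rule)
  for (fn in list(glcmFeatures, glrlmFeatures, glszmFeatures, gldmFeatures))
    expect_equal(fn(lev), fn(levR), tolerance = 1e-12)

  levS <- discretize(img + 100, mask, rule)
  expect_identical(as.vector(lev), as.vector(levS))
  f0 <- firstOrderFeatures(img, mask, rule = rule)
  f1 <- firstOrderFeatures(img + 100, mask, rule = rule)
  expect_equal(f1[["Mean"]], f0[["Mean"]] + 100)
  expect_equal(f1[["Entropy"]], f0[["Entropy"]])
})

test_that("matrix normalizations sum to one", {
  set.seed(11)
  lev <- randomLevels(10, 10, 4)
  ng <- attr(lev, "nGray")
  P <- radstab:::.cppGlcm(lev, ng, 0L, 1L)
  expect_equal(sum(P / sum(P)), 1, tolerance = 1e-12)
  R <- radstab:::.cppGlrlm(lev, ng, 1L, 0L)
  expect_equal(sum(R / sum(R)), 1, tolerance = 1e-12)
  Z <- radstab:::.cppGlszm(lev, ng)
  expect_equal(sum(Z / sum(Z)), 1, tolerance = 1e-12)
  D <- radstab:::.cppGldm(lev, ng, 0L)
  expect_equal(sum(D), sum(lev > 0))
})

test_that("wavelet sub-bands behave like separable low/high-pass filters", {
  const <- matrix(5, 16, 16)
  w <- waveletDecompose(const)
  expect_lt(max(abs(w$LH)), 1e-8)
  expect_lt(max(abs(w$HL)), 1e-8)
  expect_lt(max(abs(w$HH)), 1e-8)
  expect_equal(w$LL, const, tolerance = 1e-10)

  ramp <- matrix(rep(seq_len(24), each = 24), 24, 24)  # varies along cols
  w2 <- waveletDecompose(ramp)
  expect_lt(sum(w2$HL^2), 1e-16)       # no vertical detail
  expect_gt(sum(w2$LH^2), 1e-4)        # horizontal detail present
  expect_error(waveletDecompose(matrix(0, 4, 4)), "8 x 8")
})

test_that("feature extraction bookkeeping: counts, rows, determinism", {
  coh <- tinyCohort(nPatients = 4, nVariants = 6)
  prep <- preprocessCohort(coh)
  cfg <- featureConfig(wavelet = TRUE)
  se <- extractFeatures(prep, cfg)
  nIntensity <- 16 + 9 + 10 + 10 + 9
  expect_equal(nrow(se), 5 * nIntensity + 8)
  expect_equal(ncol(se), length(prep$frames) * 7)  # 1 manual + 6 variants

  # permuting lesion order yields the same table after sorting
  se2 <- extractFeatures(rev(prep$frames), cfg)
  k <- colnames(se)
  expect_equal(SummarizedExperiment::assay(se)[, k],
               SummarizedExperiment::assay(se2)[, k])
})

test_that("feature tables round-trip through long-format CSV", {
  coh <- tinyCohort(nPatients = 3, nVariants = 3)
  se <- extractFeatures(preprocessCohort(coh), tinyFeatureConfig())
  tmp <- tempfile(fileext = ".csv")
  writeFeatureCSV(se, tmp)
  se2 <- readFeatureCSV(tmp)
  expect_equal(SummarizedExperiment::assay(se)[, colnames(se)],
               SummarizedExperiment::assay(se2)[rownames(se), colnames(se)])
  long <- read.csv(tmp)
  expect_false(anyDuplicated(long[, c("lesion_id", "segmentation_id",
                                      "feature_name")]) > 0)
})
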