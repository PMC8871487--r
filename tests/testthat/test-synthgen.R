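test_that("a circular phantom rasterizes to a disk of the requested size", {
  cs <- makePhantom(phantomSpec(imageSize = 64, axes = c(10, 10),
                                irregularity = 0, boundarySigma = 0,
                                seed = 3))
  m <- cs@manualMasks[[1]]
  expect_lt(abs(sum(m) - pi * 100) / (pi * 100), 0.05)
  expect_equal(radstab:::nComponents(m, 4L), 1)
})

test_that("the mask is noise-free: texture seeds change only the interior", {
  a <- makePhantom(phantomSpec(seed = 1, irregularity = 0.2))
  b <- makePhantom(phantomSpec(seed = 2, irregularity = 0.2))
  expect_identical(a@manualMasks[[1]], b@manualMasks[[1]])
  expect_false(identical(a@image, b@image))
})

test_that("elliptical phantoms have the requested axis ratio", {
  cs <- makePhantom(phantomSpec(imageSize = 96, axes = c(20, 10),
                                irregularity = 0, boundarySigma = 0))
  mom <- radstab:::maskMoments(cs@manualMasks[[1]], c(1, 1))
  ratio <- sqrt(mom$lambda[1] / mom$lambda[2])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("interior texture honours the requested mean and SD", {
  cs <- makePhantom(phantomSpec(imageSize = 96, axes = c(18, 18),
                                textureMean = 100, textureSd = 10,
                                boundarySigma = 0, seed = 9))
  core <- radstab:::signedDistance(cs@manualMasks[[1]]) > 4
  expect_lt(abs(mean(cs@image[core]) - 100), 3)
  expect_lt(abs(sd(cs@image[core]) - 10), 3)
})

test_that("oversized lesions are rejected with a sizing error", {
  expect_error(makePhantom(phantomSpec(imageSize = 32, axes = c(20, 20))),
               "fit")
})

test_that("zero-amplitude perturbation reproduces the source mask", {
  cs <- diskCase()
  out <- perturbMask(cs, perturbationSpec(nVariants = 10, amplitude = 0))
  for (v in out@variantMasks)
    expect_identical(v, cs@manualMasks[[1]])
})

test_that("perturbed variants stay connected, within the Dice band, and
           overlap degrades as amplitude grows", {
  cs <- diskCase(radius = 10)
  meanDice <- vapply(c(1, 2, 4), function(amp) {
    d <- numeric(0)
    for (seed in 1:8) {
      out <- perturbMask(cs, perturbationSpec(nVariants = 8,
                                              amplitude = amp,
                                              noiseCorrelation = 2,
                                              seed = seed))
      for (v in out@variantMasks) {
        expect_equal(radstab:::nComponents(v, 4L), 1)
        d <- c(d, diceCoefficient(v, cs@manualMasks[[1]]))
      }
    }
    expect_true(all(d > 0.6))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(meanDice) < 0))
})

test_that("displacement is larger along the blurred half of the boundary", {
  cs <- makePhantom(phantomSpec(imageSize = 72, axes = c(12, 12),
                                irregularity = 0,
                                boundarySigma = c(3, 0.3), seed = 4))
  src <- cs@manualMasks[[1]]
  out <- perturbMask(cs, perturbationSpec(nVariants = 100, amplitude = 2,
                                          noiseCorrelation = 2,
                                          gradientModulation = TRUE,
                                          seed = 7))
  # per-variant area of disagreement with the source, split by side: the
  # disagreement integrates |boundary displacement| along each half
  ctr <- (ncol(src) + 1) / 2
  left <- col(src) < ctr     # blurred side
  flipAreaL <- vapply(out@variantMasks,
                      function(v) sum(xor(v, src) & left), numeric(1))
  flipAreaR <- vapply(out@variantMasks,
                      function(v) sum(xor(v, src) & !left), numeric(1))
  wt <- wilcox.test(flipAreaL, flipAreaR, paired = TRUE,
                    alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})

test_that("survival generator matches its exponential null model", {
  feats <- data.frame(patient_id = as.character(1:2000), f = rnorm(2000))
  rec <- simulateSurvival(feats,
                          survivalGenSpec(beta = c(f = 0),
                                          baselineRate = 0.5,
                                          censorRate = 0,
                                          adminCensorTime = 1e6, seed = 2))
  expect_true(all(rec$event == 1))
  ks <- ks.test(rec$time_years, "pexp", 0.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("survival generator reproduces a known hazard ratio", {
  feats <- data.frame(patient_id = as.character(1:2000),
                      g = rep(0:1, 1000))
  rec <- simulateSurvival(feats,
                          survivalGenSpec(beta = c(g = log(2)),
                                          baselineRate = 0.3,
                                          censorRate = 0,
                                          adminCensorTime = 1e6, seed = 5))
  # with standardized 0/1 feature, group hazards differ by exp(beta)
  rate <- tapply(rec$time_years, feats$g, function(t) 1 / mean(t))
  expect_lt(abs(rate[["1"]] / rate[["0"]] - 2) / 2, 0.15)
})

test_that("administrative censoring truncates every follow-up time", {
  feats <- data.frame(patient_id = as.character(1:200), f = rnorm(200))
  rec <- simulateSurvival(feats,
                          survivalGenSpec(beta = c(f = 0.5),
                                          baselineRate = 0.1,
                                          censorRate = 0.05,
                                          adminCensorTime = 3, seed = 1))
  expect_true(all(rec$time_years <= 3))
  expect_true(all(rec$event %in% 0:1))
})

test_that("missing beta features are reported by name", {
  feats <- data.frame(patient_id = "1", f = 1)
  expect_error(simulateSurvival(feats,
                                survivalGenSpec(beta = c(nope = 1))),
               "nope")
})

test_that("cohorts are reproducible and reject degenerate sizes", {
  a <- tinyCohort(nPatients = 4, nVariants = 5, masterSeed = 7)
  b <- tinyCohort(nPatients = 4, nVariants = 5, masterSeed = 7)
  expect_equal(a@cases[[2]]@image, b@cases[[2]]@image)
  expect_identical(a@cases[[3]]@variantMasks, b@cases[[3]]@variantMasks)
  expect_identical(cohortSurvival(a), cohortSurvival(b))
  expect_equal(length(a@cases[[1]]@variantMasks), 5)
  expect_error(makeCohort(1), "nPatients")
})

test_that("manual raters are low-amplitude perturbations of the truth", {
  coh <- makeCohort(3, phantom = phantomSpec(imageSize = 64),
                    perturb = perturbationSpec(nVariants = 3),
                    nManual = 4, manualAmplitude = 0.5,
                    variation = cohortVariation(axesFactor = c(0.8, 1.2)),
                    masterSeed = 2)
  cs <- coh@cases[[1]]
  expect_length(cs@manualMasks, 4)
  dice <- vapply(cs@manualMasks[-1],
                 diceCoefficient, numeric(1), b = cs@truth$mask)
  expect_true(all(dice > 0.85))
})
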