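#' Phantom specification
#'
#' Parameters of one synthetic lesion phantom: a textured elliptical lesion
#' with an optionally irregular, optionally blurred boundary embedded in a
#' textured background.
#'
#' @param imageSize pixels per side of the (square) image.
#' @param pixelSpacing mm per pixel (isotropic).
#' @param axes numeric(2), ellipse semi-axes in mm (major, minor).
#' @param irregularity dimensionless amplitude (>= 0) of a low-order random
#'   Fourier modulation of the boundary radius; 0 gives an exact ellipse.
#' @param angle rotation of the major axis, radians.
#' @param textureMean,textureSd mean and SD of lesion interior intensity
#'   (arbitrary units).
#' @param textureCorrelation spatial correlation length of the interior
#'   texture, mm.
#' @param boundarySigma edge blur sigma in mm. Length 1 for a uniform
#'   boundary; length 2 blurs the left and right half of the lesion with
#'   different sigmas (used to study sharpness-dependent outline variability).
#' @param backgroundMean,backgroundSd background intensity mean and SD.
#' @param backgroundCorrelation background correlation length, mm.
#' @param seed integer seed for the texture fields.
#' @param shapeSeed integer seed for the irregular-boundary coefficients; the
#'   mask depends only on the geometry parameters and this seed, never on
#'   \code{seed}, so two phantoms differing only in \code{seed} share the
#'   identical mask.
#'
#' @return a list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(imageSize = 96, pixelSpacing = 1,
                        axes = c(10, 8), irregularity = 0.15, angle = 0,
                        textureMean = 60, textureSd = 20,
                        textureCorrelation = 2,
                        boundarySigma = 1,
                        backgroundMean = -20, backgroundSd = 15,
                        backgroundCorrelation = 3,
                        seed = 1L, shapeSeed = 1L) {
  spec <- list(imageSize = as.integer(imageSize),
               pixelSpacing = pixelSpacing, axes = axes,
               irregularity = irregularity, angle = angle,
               textureMean = textureMean, textureSd = textureSd,
               textureCorrelation = textureCorrelation,
               boundarySigma = boundarySigma,
               backgroundMean = backgroundMean, backgroundSd = backgroundSd,
               backgroundCorrelation = backgroundCorrelation,
               seed = as.integer(seed), shapeSeed = as.integer(shapeSeed))
  stopifnot(spec$imageSize > 0, spec$pixelSpacing > 0,
            length(spec$axes) == 2, all(spec$axes > 0),
            spec$irregularity >= 0, spec$textureCorrelation >= 0,
            all(spec$boundarySigma >= 0),
            length(spec$boundarySigma) %in% c(1, 2))
  class(spec) <- "phantomSpec"
  spec
}

#' Perturbation specification
#'
#' Parameters of the stochastic outline perturbation that emulates a
#' generative segmentation model producing plausible alternative outlines:
#' the source mask's signed distance transform is thresholded after adding a
#' spatially correlated Gaussian displacement field.
#'
#' @param nVariants number of perturbed outlines to draw (default 100).
#' @param amplitude SD of the boundary displacement field, mm; 0 reproduces
#'   the source mask exactly in every variant.
#' @param noiseCorrelation correlation length of the displacement field, mm.
#' @param gradientModulation logical; scale the displacement by the inverse
#'   local image-gradient magnitude, so fuzzy (low-gradient) boundary
#'   segments move more than sharp ones.
#' @param diceMin minimum Dice overlap with the source mask; variants below
#'   it are resampled.
#' @param retryLimit resampling attempts before an error.
#' @param seed integer seed.
#'
#' @return a list of class \code{perturbationSpec}.
#' @export
perturbationSpec <- function(nVariants = 100, amplitude = 2,
                             noiseCorrelation = 2,
                             gradientModulation = TRUE,
                             diceMin = 0.6, retryLimit = 10, seed = 1L) {
  spec <- list(nVariants = as.integer(nVariants), amplitude = amplitude,
               noiseCorrelation = noiseCorrelation,
               gradientModulation = isTRUE(gradientModulation),
               diceMin = diceMin, retryLimit = as.integer(retryLimit),
               seed = as.integer(seed))
  stopifnot(spec$nVariants >= 1, spec$amplitude >= 0,
            spec$noiseCorrelation >= 0, spec$retryLimit >= 1)
  class(spec) <- "perturbationSpec"
  spec
}

#' Survival-generation specification
#'
#' Exponential proportional-hazards ground truth: event times are drawn with
#' hazard \code{baselineRate * exp(x . beta)} on internally standardized
#' features, censored by an independent exponential censoring process and an
#' administrative cutoff.
#'
#' @param beta named numeric: feature name -> log hazard ratio.
#' @param baselineRate baseline events per year (> 0).
#' @param censorRate independent censoring events per year (>= 0).
#' @param adminCensorTime administrative censoring horizon, years.
#' @param seed integer seed.
#'
#' @return a list of class \code{survivalGenSpec}.
#' @export
survivalGenSpec <- function(beta = c(area = 0.3, mean_intensity = 0.55,
                                     major_axis = 0.2),
                            baselineRate = 0.35, censorRate = 0.05,
                            adminCensorTime = 5, seed = 1L) {
  spec <- list(beta = beta, baselineRate = baselineRate,
               censorRate = censorRate, adminCensorTime = adminCensorTime,
               seed = as.integer(seed))
  stopifnot(spec$baselineRate > 0, spec$censorRate >= 0,
            spec$adminCensorTime > 0, length(spec$beta) >= 1,
            !is.null(names(spec$beta)))
  class(spec) <- "survivalGenSpec"
  spec
}

# Ground-truth boundary radius (mm) as a function of polar angle.
phantomRadius <- function(spec, theta) {
  a <- spec$axes[1]; b <- spec$axes[2]
  th <- theta - spec$angle
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  if (spec$irregularity > 0) {
    set.seed(spec$shapeSeed)
    ks <- 2:6
    ca <- rnorm(length(ks)) / ks
    cb <- rnorm(length(ks)) / ks
    mod <- rowSums(outer(theta, ks, function(t, k) cos(k * t)) %*%
                     diag(ca, length(ks)) +
                   outer(theta, ks, function(t, k) sin(k * t)) %*%
                     diag(cb, length(ks)))
    mod <- mod / max(1e-9, max(abs(mod)))
    r <- r * (1 + spec$irregularity * mod)
  }
  r
}

#' Generate a synthetic lesion phantom
#'
#' Rasterizes the ground-truth outline on the pixel grid, fills the interior
#' and background with spatially correlated Gaussian texture, and blends the
#' two across the boundary with the requested blur. The resulting mask is the
#' noiseless ground truth and is stored both as the first manual mask and
#' under \code{truth$mask}.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param lesionId,patientId identifiers.
#' @param modality \code{"CT-like"} or \code{"MRI-like"} tag.
#' @return a \code{\link{LesionCase-class}} without variant masks.
#' @export
makePhantom <- function(spec, lesionId = "lesion1", patientId = lesionId,
                        modality = "CT-like") {
  stopifnot(inherits(spec, "phantomSpec"))
  n <- spec$imageSize
  sp <- spec$pixelSpacing
  ctr <- (n + 1) / 2
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  rows <- matrix(rep(seq_len(n), n), n, n)
  dx <- (cols - ctr) * sp
  dy <- (rows - ctr) * sp
  theta <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  mask <- rr <= matrix(phantomRadius(spec, as.vector(theta)), n, n)

  if (!any(mask))
    stop("lesion is empty at this image size/spacing")
  hit <- which(mask, arr.ind = TRUE)
  margin <- 2 + ceiling(3 * max(spec$boundarySigma) / sp)
  if (min(hit) <= margin || max(hit) > n - margin)
    stop("lesion does not fit in the image (increase imageSize)")
  mask <- cleanMask(mask)

  set.seed(spec$seed)
  lesionField <- spec$textureMean + spec$textureSd *
    correlatedField(n, n, spec$textureCorrelation / sp)
  bgField <- spec$backgroundMean + spec$backgroundSd *
    correlatedField(n, n, spec$backgroundCorrelation / sp)

  maskNum <- matrix(as.numeric(mask), n, n)
  sig <- spec$boundarySigma / sp
  if (length(sig) == 1) {
    alpha <- if (sig > 0) gaussianBlur(maskNum, sig) else maskNum
  } else {
    aL <- if (sig[1] > 0) gaussianBlur(maskNum, sig[1]) else maskNum
    aR <- if (sig[2] > 0) gaussianBlur(maskNum, sig[2]) else maskNum
    w <- 1 / (1 + exp((cols - ctr) / 1.5))  # ~1 left half, ~0 right half
    alpha <- w * aL + (1 - w) * aR
  }
  img <- alpha * lesionField + (1 - alpha) * bgField

  new("LesionCase", lesionId = lesionId, patientId = patientId,
      modality = modality, image = img,
      spacing = c(sp, sp), manualMasks = list(mask),
      variantMasks = list(), truth = list(spec = spec, mask = mask))
}

# Draw one perturbed outline from a source mask. Internal.
perturbOnce <- function(sourceMask, sdistMm, modField, amplitudeMm,
                        corrPx) {
  if (amplitudeMm <= 0) return(sourceMask)
  noise <- correlatedField(nrow(sourceMask), ncol(sourceMask), corrPx)
  cand <- (sdistMm + amplitudeMm * noise * modField) > 0
  if (!any(cand)) return(NULL)
  cleanMask(cand)
}

#' Perturb a lesion's outline into plausible segmentation variants
#'
#' Thresholds the ground-truth mask's signed distance transform at a
#' spatially correlated Gaussian displacement field, keeping the largest
#' 4-connected component and filling holes. With
#' \code{gradientModulation = TRUE} the displacement is scaled by the inverse
#' smoothed image-gradient magnitude, so outlines vary more along fuzzy
#' boundary segments, emulating the behaviour of generative segmentation
#' models whose samples disperse where the image is ambiguous.
#'
#' @param case a \code{\link{LesionCase-class}} with at least one manual mask.
#' @param pspec a \code{\link{perturbationSpec}}.
#' @param sourceMask optional explicit source mask (defaults to the ground
#'   truth if present, else the first manual mask).
#' @return the case with \code{variantMasks} filled (\code{nVariants} masks).
#' @export
perturbMask <- function(case, pspec, sourceMask = NULL) {
  stopifnot(is(case, "LesionCase"), inherits(pspec, "perturbationSpec"))
  src <- sourceMask
  if (is.null(src))
    src <- if (!is.null(case@truth$mask)) case@truth$mask else
      case@manualMasks[[1]]
  sp <- case@spacing[1]
  sdistMm <- signedDistance(src) * sp
  corrPx <- pspec$noiseCorrelation / sp

  modField <- matrix(1, nrow(src), ncol(src))
  if (pspec$gradientModulation && pspec$amplitude > 0) {
    g <- gaussianBlur(gradientMagnitude(case@image), 1)
    band <- abs(sdistMm) <= max(2, pspec$amplitude)
    g0 <- median(g[band])
    m <- 1 / (1 + g / max(g0, .Machine$double.eps))
    modField <- m / mean(m[band])
  }

  set.seed(pspec$seed)
  variants <- vector("list", pspec$nVariants)
  for (v in seq_len(pspec$nVariants)) {
    ok <- FALSE
    for (try in seq_len(pspec$retryLimit)) {
      cand <- perturbOnce(src, sdistMm, modField, pspec$amplitude, corrPx)
      if (!is.null(cand) && any(cand) &&
          diceCoefficient(cand, src) >= pspec$diceMin) {
        variants[[v]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("perturbation failed for variant ", v, " after ",
           pspec$retryLimit, " retries (amplitude too large for lesion ",
           case@lesionId, "?)")
  }
  case@variantMasks <- variants
  validObject(case)
  case
}

#' Simulate right-censored survival times from features
#'
#' Event times follow an exponential proportional-hazards model: hazard
#' \code{baselineRate * exp(lp)} with linear predictor \code{lp = z . beta}
#' on mean-centered features \code{z}, so each \code{beta} is the log hazard
#' ratio per raw feature unit (a 0/1 feature with \code{beta = log 2} yields
#' a hazard ratio of 2 between its groups) and the baseline rate applies to
#' the average patient. Observed time is the minimum of the event time, an
#' independent exponential censoring time and the administrative horizon;
#' the event indicator is 1 only when the event came first.
#'
#' @param features data.frame or matrix (patients x features) with row names
#'   or a \code{patient_id} column.
#' @param sspec a \code{\link{survivalGenSpec}}.
#' @return data.frame: patient_id, time_years, event (0/1).
#' @export
simulateSurvival <- function(features, sspec) {
  stopifnot(inherits(sspec, "survivalGenSpec"))
  feats <- as.data.frame(features)
  if ("patient_id" %in% colnames(feats)) {
    ids <- as.character(feats$patient_id)
    feats$patient_id <- NULL
  } else {
    ids <- rownames(feats)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(feats)))
  }
  missing <- setdiff(names(sspec$beta), colnames(feats))
  if (length(missing))
    stop("features named in beta are missing from the table: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(feats[, names(sspec$beta), drop = FALSE])
  Z <- scale(X, center = TRUE, scale = FALSE)
  lp <- as.vector(Z %*% sspec$beta)

  set.seed(sspec$seed)
  n <- nrow(feats)
  tEvent <- rexp(n, rate = sspec$baselineRate * exp(lp))
  tCensor <- if (sspec$censorRate > 0) rexp(n, rate = sspec$censorRate)
             else rep(Inf, n)
  time <- pmin(tEvent, tCensor, sspec$adminCensorTime)
  time <- pmax(time, 1e-6)
  event <- as.integer(tEvent <= pmin(tCensor, sspec$adminCensorTime))
  data.frame(patient_id = ids, time_years = time, event = event,
             stringsAsFactors = FALSE)
}

#' Between-patient variation of phantom parameters within a cohort
#'
#' Ranges from which each patient's lesion geometry and texture are drawn,
#' creating the between-subject variance that reliability and survival
#' analyses require.
#'
#' @param axesFactor multiplicative range applied to the template semi-axes.
#' @param irregularityRange range of boundary irregularity.
#' @param sigmaRange range of boundary blur sigma, mm.
#' @param meanJitterSd SD of an additive per-patient shift of the lesion
#'   texture mean (intensity units).
#' @return a list of class \code{cohortVariation}.
#' @export
cohortVariation <- function(axesFactor = c(0.4, 2.2),
                            irregularityRange = c(0.05, 0.25),
                            sigmaRange = c(0.4, 2.0),
                            meanJitterSd = 25) {
  out <- list(axesFactor = axesFactor,
              irregularityRange = irregularityRange,
              sigmaRange = sigmaRange, meanJitterSd = meanJitterSd)
  class(out) <- "cohortVariation"
  out
}

# True (noiseless) per-patient features used to drive survival simulation.
truthFeatures <- function(cases) {
  rows <- lapply(cases, function(cs) {
    m <- cs@truth$mask
    sp <- cs@spacing[1]
    mom <- maskMoments(m, cs@spacing)
    data.frame(patient_id = cs@patientId,
               area = sum(m) * sp * sp,
               mean_intensity = mean(cs@image[m]),
               major_axis = 4 * sqrt(mom$lambda[1]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws one lesion per patient with per-patient geometry/texture variation,
#' perturbs each ground-truth outline into \code{nManual} low-amplitude
#' "manual rater" masks (for \code{nManual > 1}; with \code{nManual = 1} the
#' manual mask is the ground truth itself) and \code{pspec$nVariants}
#' higher-amplitude "automatic" variants, and simulates survival from the
#' noiseless ground-truth features.
#'
#' @param nPatients number of patients (>= 2).
#' @param phantom template \code{\link{phantomSpec}}.
#' @param perturb \code{\link{perturbationSpec}} for the automatic variants.
#' @param survspec \code{\link{survivalGenSpec}}; its \code{beta} names must
#'   be among \code{area}, \code{mean_intensity}, \code{major_axis} (the
#'   stable ground-truth features) or any column of a user-supplied truth
#'   table.
#' @param nManual number of manual raters (>= 1).
#' @param manualAmplitude displacement SD (mm) for manual-rater masks when
#'   \code{nManual > 1}.
#' @param variation a \code{\link{cohortVariation}}.
#' @param modality cohort modality tag.
#' @param masterSeed integer; all per-stage seeds derive from it.
#' @return a \code{\link{RadiomicsCohort-class}}.
#' @export
makeCohort <- function(nPatients, phantom = phantomSpec(),
                       perturb = perturbationSpec(),
                       survspec = survivalGenSpec(),
                       nManual = 1, manualAmplitude = 0.5,
                       variation = cohortVariation(),
                       modality = "CT-like", masterSeed = 1L) {
  if (nPatients < 2)
    stop("nPatients must be >= 2 (survival cross-validation needs a cohort)")
  cases <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    set.seed(deriveSeed(masterSeed, "phantom", i))
    fac <- runif(2, variation$axesFactor[1], variation$axesFactor[2])
    ps <- phantom
    ps$axes <- sort(phantom$axes * fac, decreasing = TRUE)
    ps$irregularity <- runif(1, variation$irregularityRange[1],
                             variation$irregularityRange[2])
    ps$angle <- runif(1, 0, pi)
    ps$boundarySigma <- runif(length(phantom$boundarySigma),
                              variation$sigmaRange[1],
                              variation$sigmaRange[2])
    ps$textureMean <- phantom$textureMean + rnorm(1, 0, variation$meanJitterSd)
    ps$seed <- deriveSeed(masterSeed, "texture", i)
    ps$shapeSeed <- deriveSeed(masterSeed, "shape", i)
    id <- sprintf("L%03d", i)
    cs <- makePhantom(ps, lesionId = id, patientId = sprintf("P%03d", i),
                      modality = modality)
    if (nManual > 1) {
      mspec <- perturbationSpec(nVariants = nManual - 1,
                                amplitude = manualAmplitude,
                                noiseCorrelation = perturb$noiseCorrelation,
                                gradientModulation =
                                  perturb$gradientModulation,
                                diceMin = perturb$diceMin,
                                seed = deriveSeed(masterSeed, "manual", i))
      tmp <- perturbMask(cs, mspec)
      cs@manualMasks <- c(cs@manualMasks, tmp@variantMasks)
    }
    vspec <- perturb
    vspec$seed <- deriveSeed(masterSeed, "variant", i)
    cs <- perturbMask(cs, vspec)
    cases[[i]] <- cs
  }
  tf <- truthFeatures(cases)
  # z-score the truth features so the default betas are per-SD effects,
  # comparable across cohort geometries
  zcols <- setdiff(colnames(tf), "patient_id")
  tf[zcols] <- lapply(tf[zcols], function(v)
    if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v))
  ss <- survspec
  ss$seed <- deriveSeed(masterSeed, "survival")
  surv <- simulateSurvival(tf, ss)
  new("RadiomicsCohort", cases = cases, survival = surv,
      metadata = list(masterSeed = masterSeed, phantom = phantom,
                      perturb = perturb, survspec = survspec,
                      nManual = nManual, manualAmplitude = manualAmplitude,
                      variation = variation, modality = modality))
}
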