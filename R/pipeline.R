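#' Default pipeline configuration
#'
#' One nested document holding every stage's parameters. Unknown keys are
#' rejected by \code{\link{validateConfig}}; a YAML file read with
#' \code{\link{readRunConfig}} is merged over these defaults.
#'
#' @return nested list of class \code{runConfig}.
#' @export
defaultConfig <- function() {
  cfg <- list(
    schemaVersion = 1,
    nPatients = 50,
    modality = "CT-like",
    masterSeed = 1,
    phantom = list(imageSize = 96, pixelSpacing = 1, axes = c(10, 8),
                   irregularity = 0.15, textureMean = 60, textureSd = 20,
                   textureCorrelation = 2, boundarySigma = 1,
                   backgroundMean = -20, backgroundSd = 15,
                   backgroundCorrelation = 3),
    perturbation = list(nVariants = 100, amplitude = 2,
                        noiseCorrelation = 2, gradientModulation = TRUE,
                        diceMin = 0.6, retryLimit = 10),
    manual = list(nManual = 4, amplitude = 0.5),
    variation = list(axesFactor = c(0.4, 2.2),
                     irregularityRange = c(0.05, 0.25),
                     sigmaRange = c(0.4, 2.0), meanJitterSd = 25),
    survivalGen = list(beta = c(area = 0.3, mean_intensity = 0.55,
                                major_axis = 0.2),
                       baselineRate = 0.35, censorRate = 0.05,
                       adminCensorTime = 5),
    preprocess = list(boxSize = NULL, minVolume = 30, sliceThickness = 1),
    features = list(bins = 32, mode = "fixed_bin_count",
                    families = c("firstorder", "shape", "glcm", "glrlm",
                                 "glszm", "gldm"),
                    wavelet = TRUE),
    signatures = list(high = 0.99, low = 0.75),
    cv = list(nFolds = 5, maxK = 5, minImprovement = 0.005,
              refitPerVariant = FALSE),
    stats = list(alpha = 0.05, nComparisons = 2)
  )
  class(cfg) <- "runConfig"
  cfg
}

#' Validate a configuration against the default schema
#'
#' Every key (at both nesting levels) must exist in
#' \code{\link{defaultConfig}}; unknown keys raise an error.
#'
#' @param config a (possibly partial) configuration list.
#' @return the config merged over the defaults, classed \code{runConfig}.
#' @export
validateConfig <- function(config) {
  ref <- unclass(defaultConfig())
  config <- unclass(config)
  bad <- setdiff(names(config), names(ref))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  merged <- ref
  for (nm in names(config)) {
    if (is.list(ref[[nm]]) && is.list(config[[nm]]) &&
        !is.null(names(ref[[nm]]))) {
      badSub <- setdiff(names(config[[nm]]), names(ref[[nm]]))
      if (length(badSub))
        stop("unknown config keys under '", nm, "': ",
             paste(badSub, collapse = ", "))
      merged[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      merged[[nm]] <- config[[nm]]
    }
  }
  if (!identical(merged$schemaVersion, 1) &&
      !identical(merged$schemaVersion, 1L))
    stop("unsupported config schema version: ", merged$schemaVersion)
  class(merged) <- "runConfig"
  merged
}

#' @rdname defaultConfig
#' @param path YAML configuration file.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$survivalGen$beta))
    raw$survivalGen$beta <- unlist(raw$survivalGen$beta)
  validateConfig(raw)
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

cohortFromConfig <- function(config, seed) {
  makeCohort(
    nPatients = config$nPatients,
    phantom = do.call(phantomSpec, config$phantom),
    perturb = do.call(perturbationSpec, config$perturbation),
    survspec = do.call(survivalGenSpec, config$survivalGen),
    nManual = config$manual$nManual,
    manualAmplitude = config$manual$amplitude,
    variation = do.call(cohortVariation, config$variation),
    modality = config$modality,
    masterSeed = seed)
}

featureConfigFromConfig <- function(config) {
  featureConfig(
    rule = discretizationRule(config$features$mode,
                              bins = config$features$bins),
    families = config$features$families,
    wavelet = config$features$wavelet)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> extract -> reliability -> survival ->
#' stats, writing every artifact (survival records, exclusion log, feature
#' table, ICC tables, C-index distributions, test report) as CSV into
#' \code{outDir} together with a manifest of the seed and config hash.
#' Stages not listed in \code{stages} are loaded from the cached artifacts
#' of a previous run in the same directory.
#'
#' @param config a \code{runConfig} (see \code{\link{defaultConfig}}).
#' @param outDir output directory (created if needed).
#' @param seed master seed; overrides \code{config$masterSeed} when given.
#' @param stages character subset of \code{c("simulate", "extract",
#'   "reliability", "survival", "stats")}; defaults to all.
#' @return invisibly, a list with the in-memory results (cohort, features,
#'   icc tables, signatures, distributions, comparison) and \code{outDir}.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = tempfile("run"),
                        seed = NULL,
                        stages = c("simulate", "extract", "reliability",
                                   "survival", "stats")) {
  config <- validateConfig(config)
  if (is.null(seed)) seed <- config$masterSeed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outDir, f)

  # --- simulate + preprocess + extract (cached as features.csv) ---
  if ("simulate" %in% stages || !file.exists(pth("cohort.rds"))) {
    cohort <- cohortFromConfig(config, seed)
    saveRDS(cohort, pth("cohort.rds"))
    write.csv(cohortSurvival(cohort), pth("survival.csv"),
              row.names = FALSE)
  } else {
    cohort <- readRDS(pth("cohort.rds"))
  }

  if ("extract" %in% stages || !file.exists(pth("features.csv"))) {
    rule <- if (is.null(config$preprocess$boxSize)) NULL else
      cropRule(config$preprocess$boxSize, config$preprocess$minVolume,
               config$preprocess$sliceThickness)
    prep <- preprocessCohort(cohort, rule,
                             minVolume = config$preprocess$minVolume,
                             sliceThickness = config$preprocess$sliceThickness)
    write.csv(prep$log, pth("exclusion_log.csv"), row.names = FALSE)
    se <- extractFeatures(prep$frames, featureConfigFromConfig(config))
    writeFeatureCSV(se, pth("features.csv"))
  } else {
    se <- readFeatureCSV(pth("features.csv"))
  }

  # --- reliability ---
  iccAuto <- iccTable(se, "automatic")
  write.csv(iccAuto, pth("icc_automatic.csv"), row.names = FALSE)
  iccManual <- NULL
  if (config$manual$nManual >= 2) {
    iccManual <- iccTable(se, "manual")
    write.csv(iccManual, pth("icc_manual.csv"), row.names = FALSE)
  }
  sig <- thresholdSignatures(iccAuto, config$signatures$high,
                             config$signatures$low)
  if (all(iccAuto$icc == 1))
    warning("perturbation amplitude 0: every ICC is 1 and the low-ICC ",
            "signature is empty")

  # --- survival ---
  records <- cohortSurvival(cohort)
  cv <- stratifiedFolds(records, config$cv$nFolds,
                        seed = deriveSeed(seed, "folds"))
  dists <- list()
  for (nm in c("high", "all", "low")) {
    feats <- sig[[nm]]
    if (!length(feats)) {
      message("signature '", nm, "' is empty; skipped")
      next
    }
    dists[[nm]] <- evaluateSignature(
      se, records, feats, cv, signatureName = nm,
      maxK = config$cv$maxK, minImprovement = config$cv$minImprovement,
      refitPerVariant = isTRUE(config$cv$refitPerVariant))
  }
  allVals <- do.call(rbind, lapply(dists, function(d)
    cbind(signature = d$signature, d$values)))
  write.csv(allVals, pth("cindex.csv"), row.names = FALSE)
  summaryTab <- do.call(rbind, lapply(dists, function(d)
    data.frame(signature = d$signature, mean = d$mean, sd = d$sd,
               sd_within_fold = d$sdWithinFold,
               n = nrow(d$values), stringsAsFactors = FALSE)))
  write.csv(summaryTab, pth("cindex_summary.csv"), row.names = FALSE)

  # --- stats ---
  comparison <- NULL
  if (length(dists) >= 2 && "all" %in% names(dists)) {
    comparison <- compareSignatures(dists$high, dists$all, dists$low,
                                    alpha = config$stats$alpha,
                                    nComparisons = config$stats$nComparisons)
    write.csv(comparison$table, pth("tests.csv"), row.names = FALSE)
  }

  manifest <- list(seed = seed, configHash = configHash(config),
                   config = unclass(config),
                   created = "run manifest",
                   nFeatures = nrow(SummarizedExperiment::assay(se)),
                   stages = stages)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), pth("manifest.json"))

  invisible(list(outDir = outDir, cohort = cohort, features = se,
                 iccAutomatic = iccAuto, iccManual = iccManual,
                 signatures = sig, distributions = dists,
                 comparison = comparison))
}

#' Build the report tables of a completed run
#'
#' Emits the per-figure data tables: ICC by quartile for manual vs
#' automatic outlines (when manual raters exist), median ICC by feature
#' family and modality, and the C-index distribution summary by signature.
#'
#' @param runDir directory written by \code{\link{runPipeline}}.
#' @return list of data.frames (also written as CSV into
#'   \code{runDir/report_*.csv}).
#' @export
makeReport <- function(runDir) {
  need <- c("icc_automatic.csv", "cindex.csv", "cindex_summary.csv")
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing))
    stop("missing stage outputs: ", paste(missing, collapse = ", "),
         "; rerun the corresponding stages")
  iccAuto <- read.csv(file.path(runDir, "icc_automatic.csv"))
  out <- list()

  manualPath <- file.path(runDir, "icc_manual.csv")
  if (file.exists(manualPath)) {
    iccManual <- read.csv(manualPath)
    iccManual$quartile <- factor(iccManual$quartile,
                                 levels = paste0("Q", 1:4))
    out$icc_quartiles <- compareManualAuto(iccManual, iccAuto)
  }

  fam <- sub("^[^.]+\\.([^.]+)\\..*$", "\\1", iccAuto$feature_name)
  famGroup <- ifelse(fam == "firstorder", "firstorder",
                     ifelse(fam == "shape2D", "shape", "graylevel"))
  med <- aggregate(icc ~ family + modality,
                   data = data.frame(icc = iccAuto$icc, family = famGroup,
                                     modality = iccAuto$modality),
                   FUN = median)
  q1 <- aggregate(icc ~ family + modality,
                  data = data.frame(icc = iccAuto$icc, family = famGroup,
                                    modality = iccAuto$modality),
                  FUN = function(v) quantile(v, 0.25, names = FALSE))
  q3 <- aggregate(icc ~ family + modality,
                  data = data.frame(icc = iccAuto$icc, family = famGroup,
                                    modality = iccAuto$modality),
                  FUN = function(v) quantile(v, 0.75, names = FALSE))
  byFam <- med
  names(byFam)[3] <- "median_icc"
  byFam$icc_q1 <- q1$icc
  byFam$icc_q3 <- q3$icc
  out$icc_by_family <- byFam

  csum <- read.csv(file.path(runDir, "cindex_summary.csv"))
  if (nrow(csum) < 3)
    csum$note <- "signature(s) missing or empty"
  out$cindex_by_signature <- csum

  for (nm in names(out))
    write.csv(out[[nm]], file.path(runDir, paste0("report_", nm, ".csv")),
              row.names = FALSE)
  out
}

#' Save / load a cohort as portable files
#'
#' Images and masks are written as NIfTI volumes (one per lesion, via the
#' RNifti package) with a JSON sidecar of metadata, and the survival records
#' as CSV, so cohorts can be inspected with standard medical-image tools.
#'
#' @param cohort a \code{\link{RadiomicsCohort-class}}.
#' @param dir target directory.
#' @return \code{saveCohort} returns \code{dir} invisibly;
#'   \code{loadCohort} the reconstructed cohort (ground-truth parameters
#'   other than the truth mask are not round-tripped).
#' @export
saveCohort <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("saveCohort requires the RNifti package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(modality = cohort@metadata$modality,
               masterSeed = cohort@metadata$masterSeed,
               lesions = list())
  for (cs in cohort@cases) {
    stack <- c(list(cs@image), lapply(cs@manualMasks, function(m) m * 1),
               lapply(cs@variantMasks, function(m) m * 1))
    arr <- array(unlist(stack),
                 c(nrow(cs@image), ncol(cs@image), length(stack)))
    f <- file.path(dir, paste0(cs@lesionId, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(cs@spacing, 1)), f)
    meta$lesions[[cs@lesionId]] <- list(
      patient_id = cs@patientId, modality = cs@modality,
      spacing = cs@spacing, n_manual = length(cs@manualMasks),
      n_variant = length(cs@variantMasks))
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "cohort.json"))
  write.csv(cohort@survival, file.path(dir, "survival.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname saveCohort
#' @export
loadCohort <- function(dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("loadCohort requires the RNifti package")
  meta <- jsonlite::fromJSON(file.path(dir, "cohort.json"),
                             simplifyVector = FALSE)
  cases <- list()
  for (id in names(meta$lesions)) {
    mi <- meta$lesions[[id]]
    arr <- RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
    img <- arr[, , 1]
    nm <- mi$n_manual
    manual <- lapply(seq_len(nm), function(i) arr[, , 1 + i] > 0.5)
    variant <- lapply(seq_len(mi$n_variant),
                      function(i) arr[, , 1 + nm + i] > 0.5)
    cases[[id]] <- new("LesionCase", lesionId = id,
                       patientId = mi$patient_id, modality = mi$modality,
                       image = img, spacing = unlist(mi$spacing),
                       manualMasks = manual, variantMasks = variant,
                       truth = list(mask = manual[[1]]))
  }
  surv <- read.csv(file.path(dir, "survival.csv"),
                   stringsAsFactors = FALSE)
  new("RadiomicsCohort", cases = cases, survival = surv,
      metadata = list(masterSeed = meta$masterSeed,
                      modality = meta$modality))
}
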