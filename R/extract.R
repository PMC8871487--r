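#' Feature-extraction configuration
#'
#' @param rule a \code{\link{discretizationRule}}.
#' @param families character subset of \code{c("firstorder", "shape", "glcm",
#'   "glrlm", "glszm", "gldm")}.
#' @param wavelet logical; also compute the intensity-based families on the
#'   four Coiflet-1 sub-bands.
#' @param gldmAlpha dependence tolerance for the GLDM family.
#' @return a list of class \code{featureConfig}.
#' @export
featureConfig <- function(rule = discretizationRule(),
                          families = c("firstorder", "shape", "glcm",
                                       "glrlm", "glszm", "gldm"),
                          wavelet = TRUE, gldmAlpha = 0L) {
  families <- match.arg(families, several.ok = TRUE)
  structure(list(rule = rule, families = families,
                 wavelet = isTRUE(wavelet), gldmAlpha = as.integer(gldmAlpha)),
            class = "featureConfig")
}

# Intensity-based families on one filtered image restricted to one mask.
intensityFeatures <- function(img, mask, config) {
  lev <- discretize(img, mask, config$rule)
  out <- numeric(0)
  fam <- config$families
  if ("firstorder" %in% fam) {
    v <- firstOrderFeatures(img, mask, levels = lev)
    out <- c(out, setNames(v, paste0("firstorder.", names(v))))
  }
  if ("glcm" %in% fam) {
    v <- glcmFeatures(lev)
    out <- c(out, setNames(v, paste0("glcm.", names(v))))
  }
  if ("glrlm" %in% fam) {
    v <- glrlmFeatures(lev)
    out <- c(out, setNames(v, paste0("glrlm.", names(v))))
  }
  if ("glszm" %in% fam) {
    v <- glszmFeatures(lev)
    out <- c(out, setNames(v, paste0("glszm.", names(v))))
  }
  if ("gldm" %in% fam) {
    v <- gldmFeatures(lev, config$gldmAlpha)
    out <- c(out, setNames(v, paste0("gldm.", names(v))))
  }
  out
}

# All features for one frame and one mask; filtered images precomputed.
maskFeatureVector <- function(filters, mask, spacing, config) {
  out <- numeric(0)
  for (fname in names(filters)) {
    v <- intensityFeatures(filters[[fname]], mask, config)
    out <- c(out, setNames(v, paste0(fname, ".", names(v))))
  }
  if ("shape" %in% config$families) {
    v <- shapeFeatures2D(mask, spacing)
    out <- c(out, setNames(v, paste0("original.shape2D.", names(v))))
  }
  out
}

#' Extract the radiomic feature table for a set of analysis frames
#'
#' Computes every configured feature for every (lesion, segmentation) pair.
#' Intensity-based families are computed on the original crop and, when
#' \code{wavelet = TRUE}, on each of the four undecimated Coiflet-1
#' sub-bands; shape features only on the original mask. Features that come
#' out non-finite for any segmentation are dropped run-wide with a message.
#'
#' @param frames list of kept \code{\link{AnalysisFrame-class}} objects (or
#'   the result of \code{\link{preprocessCohort}}).
#' @param config a \code{\link{featureConfig}}.
#' @return a \code{SummarizedExperiment}: assay \code{"features"} (features
#'   x segmentation-samples), colData with lesion_id, patient_id,
#'   segmentation_id, segmentation_type and modality.
#' @export
extractFeatures <- function(frames, config = featureConfig()) {
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  stopifnot(length(frames) >= 1)
  cols <- list()
  meta <- list()
  for (fr in frames) {
    stopifnot(is(fr, "AnalysisFrame"), fr@status == "kept")
    filters <- list(original = fr@image)
    if (config$wavelet) {
      if (nrow(fr@image) >= 8 && ncol(fr@image) >= 8) {
        wb <- waveletDecompose(fr@image)
        names(wb) <- paste0("wavelet-", names(wb))
        filters <- c(filters, wb)
      } else {
        message("frame ", fr@lesionId,
                " smaller than 8 x 8: wavelet bands skipped")
      }
    }
    for (segId in names(fr@masks)) {
      key <- paste(fr@lesionId, segId, sep = ".")
      cols[[key]] <- maskFeatureVector(filters, fr@masks[[segId]],
                                       fr@spacing, config)
      meta[[key]] <- data.frame(
        lesion_id = fr@lesionId, patient_id = fr@patientId,
        segmentation_id = segId,
        segmentation_type = if (grepl("^manual", segId)) "manual"
                            else "automatic",
        modality = fr@modality, stringsAsFactors = FALSE)
    }
  }
  featNames <- names(cols[[1]])
  mat <- vapply(cols, function(v) {
    stopifnot(identical(names(v), featNames))
    unname(v)
  }, numeric(length(featNames)))
  rownames(mat) <- featNames
  bad <- !apply(is.finite(mat), 1, all)
  if (any(bad)) {
    message("dropping ", sum(bad), " feature(s) with non-finite values: ",
            paste(head(featNames[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ...")
    mat <- mat[!bad, , drop = FALSE]
  }
  cd <- do.call(rbind, meta)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    colData = S4Vectors::DataFrame(cd))
}

#' Write / read a feature table as long-format CSV
#'
#' @param se feature \code{SummarizedExperiment} from
#'   \code{\link{extractFeatures}}.
#' @param path CSV path.
#' @return \code{writeFeatureCSV} returns \code{path} invisibly;
#'   \code{readFeatureCSV} the reconstructed \code{SummarizedExperiment}.
#' @export
writeFeatureCSV <- function(se, path) {
  mat <- SummarizedExperiment::assay(se, "features")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  long <- data.frame(
    lesion_id = rep(cd$lesion_id, each = nrow(mat)),
    patient_id = rep(cd$patient_id, each = nrow(mat)),
    segmentation_id = rep(cd$segmentation_id, each = nrow(mat)),
    segmentation_type = rep(cd$segmentation_type, each = nrow(mat)),
    modality = rep(cd$modality, each = nrow(mat)),
    feature_name = rep(rownames(mat), ncol(mat)),
    value = as.vector(mat), stringsAsFactors = FALSE)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  keys <- paste(long$lesion_id, long$segmentation_id, sep = ".")
  ukeys <- unique(keys)
  feats <- unique(long$feature_name)
  mat <- matrix(NA_real_, length(feats), length(ukeys),
                dimnames = list(feats, ukeys))
  mat[cbind(match(long$feature_name, feats), match(keys, ukeys))] <-
    long$value
  first <- long[!duplicated(keys), ]
  cd <- S4Vectors::DataFrame(
    lesion_id = first$lesion_id, patient_id = first$patient_id,
    segmentation_id = first$segmentation_id,
    segmentation_type = first$segmentation_type,
    modality = first$modality, row.names = ukeys)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), colData = cd)
}
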