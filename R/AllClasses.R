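#' LesionCase: one lesion with its image, manual and variant outlines
#'
#' Container for a single lesion: the 2D intensity image, pixel spacing,
#' at least one "manual" segmentation mask, any number of perturbed variant
#' masks, and the generating ground truth (for synthetic phantoms).
#'
#' @slot lesionId character(1), unique within a cohort.
#' @slot patientId character(1).
#' @slot modality character(1), `"CT-like"` or `"MRI-like"`.
#' @slot image numeric matrix of intensities.
#' @slot spacing numeric(2), pixel spacing in mm (row, column).
#' @slot manualMasks list of logical matrices, length >= 1.
#' @slot variantMasks list of logical matrices (possibly empty).
#' @slot truth list of generating parameters; for phantoms contains the
#'   noiseless ground-truth mask under `$mask`.
#'
#' @exportClass LesionCase
setClass("LesionCase",
  representation(
    lesionId = "character",
    patientId = "character",
    modality = "character",
    image = "matrix",
    spacing = "numeric",
    manualMasks = "list",
    variantMasks = "list",
    truth = "list"
  )
)

setValidity("LesionCase", function(object) {
  msg <- character()
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive numbers (mm)")
  if (length(object@manualMasks) < 1)
    msg <- c(msg, "at least one manual mask is required")
  for (m in c(object@manualMasks, object@variantMasks)) {
    if (!all(dim(m) == dim(object@image)))
      msg <- c(msg, "all masks must share the image grid")
    else if (!any(m))
      msg <- c(msg, "masks must be nonempty")
  }
  if (!(object@modality %in% c("CT-like", "MRI-like")))
    msg <- c(msg, "modality must be 'CT-like' or 'MRI-like'")
  if (length(msg)) msg else TRUE
})

#' @describeIn LesionCase-class display a short summary
#' @param object a \code{LesionCase}
#' @export
setMethod("show", "LesionCase", function(object) {
  cat("LesionCase", object@lesionId, "(patient", object@patientId,
      ",", object@modality, ")\n")
  cat("  image:", nrow(object@image), "x", ncol(object@image),
      "px, spacing", paste(object@spacing, collapse = " x "), "mm\n")
  cat("  masks:", length(object@manualMasks), "manual,",
      length(object@variantMasks), "variant\n")
})

#' RadiomicsCohort: a set of lesion cases plus survival records
#'
#' @slot cases list of \code{LesionCase}, one per patient by default.
#' @slot survival data.frame with columns patient_id, time_years, event.
#' @slot metadata list: generating specs, master seed, modality tag.
#'
#' @exportClass RadiomicsCohort
setClass("RadiomicsCohort",
  representation(
    cases = "list",
    survival = "data.frame",
    metadata = "list"
  )
)

setValidity("RadiomicsCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@cases, is, logical(1), "LesionCase")))
    msg <- c(msg, "cases must all be LesionCase objects")
  ids <- vapply(object@cases, function(x) x@lesionId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "lesion ids must be unique within a cohort")
  if (nrow(object@survival) > 0 &&
      !all(c("patient_id", "time_years", "event") %in%
           colnames(object@survival)))
    msg <- c(msg, "survival needs columns patient_id, time_years, event")
  if (length(msg)) msg else TRUE
})

#' @describeIn RadiomicsCohort-class display a short summary
#' @param object a \code{RadiomicsCohort}
#' @export
setMethod("show", "RadiomicsCohort", function(object) {
  cat("RadiomicsCohort with", length(object@cases), "lesions\n")
  if (length(object@cases)) {
    nv <- lengths(lapply(object@cases, function(x) x@variantMasks))
    cat("  variant masks per lesion:", paste(range(nv), collapse = "-"), "\n")
  }
  cat("  survival records:", nrow(object@survival), "\n")
})

#' @rdname cohortAccessors
#' @param cohort a \code{RadiomicsCohort}
#' @return \code{cohortCases} the list of \code{LesionCase};
#'   \code{cohortSurvival} the survival data.frame.
#' @export
cohortCases <- function(cohort) cohort@cases

#' Accessors for RadiomicsCohort
#' @rdname cohortAccessors
#' @export
cohortSurvival <- function(cohort) cohort@survival

#' AnalysisFrame: a cropped 2D analysis window around one lesion
#'
#' Result of applying the cropping and exclusion rules to a lesion: the image
#' crop, all segmentation masks cropped to the same window, the crop offset,
#' and the exclusion status.
#'
#' @slot lesionId,patientId,modality character(1).
#' @slot image cropped intensity matrix.
#' @slot spacing numeric(2) mm.
#' @slot masks named list of cropped logical masks (\code{manual1}, ...,
#'   \code{variant1}, ...).
#' @slot offset integer(2): (row, col) of the crop's top-left pixel in the
#'   original image, 1-based.
#' @slot status character(1): \code{kept}, \code{too_small},
#'   \code{exceeds_box} or \code{multiple_lesions}.
#'
#' @exportClass AnalysisFrame
setClass("AnalysisFrame",
  representation(
    lesionId = "character",
    patientId = "character",
    modality = "character",
    image = "matrix",
    spacing = "numeric",
    masks = "list",
    offset = "integer",
    status = "character"
  )
)

setValidity("AnalysisFrame", function(object) {
  msg <- character()
  if (!(object@status %in%
        c("kept", "too_small", "exceeds_box", "multiple_lesions")))
    msg <- c(msg, "unknown exclusion status")
  if (object@status == "kept") {
    for (m in object@masks)
      if (!all(dim(m) == dim(object@image)))
        msg <- c(msg, "cropped masks must match the cropped image")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn AnalysisFrame-class display a short summary
#' @param object an \code{AnalysisFrame}
#' @export
setMethod("show", "AnalysisFrame", function(object) {
  cat("AnalysisFrame", object@lesionId, "[", object@status, "]",
      nrow(object@image), "x", ncol(object@image), "px,",
      length(object@masks), "masks\n")
})
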