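#' Cropping rule
#'
#' @param boxSize square crop side, pixels.
#' @param minVolume minimum lesion volume in mm^3 (default 30); for 2D
#'   phantoms volume is area x \code{sliceThickness}.
#' @param sliceThickness assumed slice thickness, mm (default 1).
#' @return a list of class \code{cropRule}.
#' @export
cropRule <- function(boxSize, minVolume = 30, sliceThickness = 1) {
  rule <- list(boxSize = as.integer(boxSize), minVolume = minVolume,
               sliceThickness = sliceThickness)
  stopifnot(rule$boxSize > 0, rule$minVolume >= 0, rule$sliceThickness > 0)
  class(rule) <- "cropRule"
  rule
}

#' Size the crop box from a cohort's lesion diameters
#'
#' The box side must exceed the mean plus two standard deviations of the
#' lesions' maximum diameters; the result is converted to pixels and rounded
#' up to the next even integer.
#'
#' @param maxDiameters numeric, maximum diameter of each lesion, mm (>= 2
#'   values).
#' @param spacing mm per pixel.
#' @return box side in pixels (even integer).
#' @export
sizeBoxes <- function(maxDiameters, spacing = 1) {
  if (length(maxDiameters) < 2)
    stop("need at least two lesion diameters to size the box")
  lim <- mean(maxDiameters) + 2 * sd(maxDiameters)
  px <- ceiling(lim / spacing)
  px + (px %% 2)
}

#' Select the axial slice of greatest cross-sectional area
#'
#' @param volumeMask 3D logical/0-1 array (x, y, slice) or a 2D matrix (then
#'   slice 1 is returned).
#' @return slice index with the most in-mask pixels; ties go to the lower
#'   index.
#' @export
selectAxialSlice <- function(volumeMask) {
  if (length(dim(volumeMask)) == 2) {
    if (!any(volumeMask)) stop("empty mask")
    return(1L)
  }
  areas <- apply(volumeMask, 3, sum)
  if (sum(areas) == 0) stop("empty mask")
  which.max(areas) # which.max returns the first maximum: lower index on ties
}

#' Crop a lesion into an analysis frame and apply the exclusion rules
#'
#' A square box is centered on the first manual mask's centroid (rounded to
#' the nearest pixel). The three exclusion rules are checked in order:
#' lesion volume below \code{minVolume} (\code{too_small}), any segmentation
#' extending beyond the box (\code{exceeds_box}), and more than one connected
#' component of the manual mask in the crop slice (\code{multiple_lesions}).
#' Boxes extending past the image border are padded with the background
#' median (with a message).
#'
#' @param case a \code{\link{LesionCase-class}}.
#' @param rule a \code{\link{cropRule}}.
#' @return an \code{\link{AnalysisFrame-class}}; only \code{kept} frames
#'   should flow into feature extraction.
#' @export
cropAndFilter <- function(case, rule) {
  stopifnot(is(case, "LesionCase"), inherits(rule, "cropRule"))
  manual <- case@manualMasks[[1]]
  if (!any(manual)) stop("empty manual mask")
  sp <- case@spacing
  box <- rule$boxSize

  emptyFrame <- function(status)
    new("AnalysisFrame", lesionId = case@lesionId,
        patientId = case@patientId, modality = case@modality,
        image = case@image, spacing = sp, masks = list(),
        offset = c(1L, 1L), status = status)

  # rule 1: too small
  volume <- sum(manual) * sp[1] * sp[2] * rule$sliceThickness
  if (volume < rule$minVolume) return(emptyFrame("too_small"))

  hit <- which(manual, arr.ind = TRUE)
  ctr <- round(colMeans(hit))
  r0 <- as.integer(ctr[1] - floor((box - 1) / 2))
  c0 <- as.integer(ctr[2] - floor((box - 1) / 2))
  rows <- r0:(r0 + box - 1)
  cols <- c0:(c0 + box - 1)

  # rule 2: any mask exceeding the box
  allMasks <- c(case@manualMasks, case@variantMasks)
  for (m in allMasks) {
    h <- which(m, arr.ind = TRUE)
    if (min(h[, 1]) < rows[1] || max(h[, 1]) > rows[box] ||
        min(h[, 2]) < cols[1] || max(h[, 2]) > cols[box])
      return(emptyFrame("exceeds_box"))
  }

  pad <- any(rows < 1) || any(cols < 1) ||
    any(rows > nrow(case@image)) || any(cols > ncol(case@image))
  cropMat <- function(m, fill) {
    out <- matrix(fill, box, box)
    rin <- rows[rows >= 1 & rows <= nrow(m)]
    cin <- cols[cols >= 1 & cols <= ncol(m)]
    out[match(rin, rows), match(cin, cols)] <- m[rin, cin]
    out
  }
  bgFill <- median(case@image[!manual])
  if (pad)
    message("crop box for ", case@lesionId,
            " extends past the image border; padded with background level")
  img <- cropMat(case@image, bgFill)

  masks <- lapply(allMasks, cropMat, fill = FALSE)
  names(masks) <- c(paste0("manual", seq_along(case@manualMasks)),
                    if (length(case@variantMasks))
                      paste0("variant", seq_along(case@variantMasks)))

  # rule 3: multiple lesions within the crop slice
  if (nComponents(masks[["manual1"]], 4L) > 1)
    return(emptyFrame("multiple_lesions"))

  new("AnalysisFrame", lesionId = case@lesionId, patientId = case@patientId,
      modality = case@modality, image = img, spacing = sp, masks = masks,
      offset = c(r0, c0), status = "kept")
}

#' Preprocess a whole cohort
#'
#' Sizes the crop box from the cohort's maximum lesion diameters (unless a
#' rule is supplied), crops every lesion and applies the exclusion rules.
#'
#' @param cohort a \code{\link{RadiomicsCohort-class}}.
#' @param rule optional \code{\link{cropRule}}; if \code{NULL} the box side
#'   comes from \code{\link{sizeBoxes}} on the manual masks.
#' @param minVolume,sliceThickness forwarded to \code{\link{cropRule}} when
#'   \code{rule} is \code{NULL}.
#' @return list with \code{frames} (kept \code{AnalysisFrame}s) and
#'   \code{log} (data.frame lesion_id, status for every lesion).
#' @export
preprocessCohort <- function(cohort, rule = NULL, minVolume = 30,
                             sliceThickness = 1) {
  stopifnot(is(cohort, "RadiomicsCohort"))
  cases <- cohort@cases
  if (is.null(rule)) {
    diams <- vapply(cases, function(cs)
      maxDiameter(cs@manualMasks[[1]], cs@spacing), numeric(1))
    box <- sizeBoxes(diams, cases[[1]]@spacing[1])
    rule <- cropRule(box, minVolume = minVolume,
                     sliceThickness = sliceThickness)
  }
  frames <- lapply(cases, cropAndFilter, rule = rule)
  status <- vapply(frames, function(f) f@status, character(1))
  log <- data.frame(
    lesion_id = vapply(cases, function(cs) cs@lesionId, character(1)),
    status = status, stringsAsFactors = FALSE)
  list(frames = frames[status == "kept"], log = log, rule = rule)
}
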