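#' One-way random-effects intraclass correlation ICC(1)
#'
#' From the one-way ANOVA decomposition of a complete subjects-by-raters
#' matrix: with between-subject mean square \eqn{MS_B} (df \eqn{n-1}) and
#' within-subject mean square \eqn{MS_W} (df \eqn{n(k-1)}),
#' \deqn{ICC(1) = (MS_B - MS_W) / (MS_B + (k-1) MS_W),}
#' ranging over \eqn{(-1/(k-1), 1]}. A matrix with zero total variance is
#' degenerate: the coefficient is defined as 1 and flagged.
#'
#' @param m numeric matrix, subjects (rows) x raters (columns), no missing
#'   cells; n >= 2, k >= 2.
#' @return numeric(1) with logical attribute \code{"degenerate"}.
#' @export
icc1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC(1) needs at least 2 subjects and 2 raters")
  if (anyNA(m)) stop("ICC(1) requires a complete design (no missing cells)")
  rowMu <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((rowMu - grand)^2) / (n - 1)
  msw <- sum((m - rowMu)^2) / (n * (k - 1))
  if (msb + msw <= .Machine$double.eps * max(1, abs(grand))^2) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (msb - msw) / (msb + (k - 1) * msw)
  attr(out, "degenerate") <- FALSE
  out
}

#' Per-feature ICC(1) reliability table
#'
#' Builds, for every feature, the lesions-by-raters matrix from one rater
#' group (all manual or all automatic segmentations), computes ICC(1), and
#' attaches quartile labels and threshold-signature membership. ICCs are
#' computed within one modality/dataset at a time; mixing modalities in one
#' call is an error.
#'
#' @param se feature \code{SummarizedExperiment} from
#'   \code{\link{extractFeatures}}.
#' @param raterGroup \code{"automatic"} (the perturbed variants) or
#'   \code{"manual"}.
#' @param dataset optional dataset tag recorded in the table.
#' @return data.frame (one row per feature, sorted by descending ICC):
#'   feature_name, dataset, modality, icc, degenerate, quartile, in_high,
#'   in_low.
#' @export
iccTable <- function(se, raterGroup = c("automatic", "manual"),
                     dataset = "synthetic") {
  raterGroup <- match.arg(raterGroup)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- cd$segmentation_type == raterGroup
  if (!any(keep)) stop("no segmentations of type '", raterGroup, "'")
  mat <- SummarizedExperiment::assay(se, "features")[, keep, drop = FALSE]
  cd <- cd[keep, ]
  modality <- unique(cd$modality)
  if (length(modality) != 1)
    stop("ICC tables are computed per modality; split the table first")
  raters <- sort(unique(cd$segmentation_id))
  lesions <- sort(unique(cd$lesion_id))
  # complete design: drop lesions missing any rater
  cnt <- table(cd$lesion_id)
  complete <- names(cnt)[cnt == length(raters)]
  if (length(complete) < length(lesions))
    warning(length(lesions) - length(complete),
            " lesion(s) dropped: incomplete rater set")
  if (length(complete) < 2 || length(raters) < 2)
    stop("need >= 2 lesions with >= 2 raters each")
  colKey <- paste(cd$lesion_id, cd$segmentation_id)
  idx <- matrix(match(outer(complete, raters, paste), colKey),
                length(complete), length(raters))

  iccs <- numeric(nrow(mat))
  degen <- logical(nrow(mat))
  for (f in seq_len(nrow(mat))) {
    v <- icc1(matrix(mat[f, idx], length(complete), length(raters)))
    iccs[f] <- v
    degen[f] <- attr(v, "degenerate")
  }
  tab <- data.frame(feature_name = rownames(mat), dataset = dataset,
                    modality = modality, icc = iccs, degenerate = degen,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$icc, tab$feature_name), ]
  rownames(tab) <- NULL
  tab$quartile <- quartileGroups(tab)
  sig <- thresholdSignatures(tab)
  tab$in_high <- tab$feature_name %in% sig$high
  tab$in_low <- tab$feature_name %in% sig$low
  tab
}

#' Reliability quartile labels
#'
#' Q1 contains the top 25 percent of features by ICC (most stable), Q4 the
#' bottom 25 percent. When the feature count is not divisible by 4 the
#' remainder is given, in order, to Q1, Q4 and Q2, so sizes differ by at
#' most one (10 features give sizes 3, 2, 2, 3). Ties in ICC are broken by
#' feature name for determinism.
#'
#' @param tab data.frame with columns \code{feature_name} and \code{icc}
#'   (>= 4 rows).
#' @return factor of labels Q1..Q4 aligned with \code{tab} rows.
#' @export
quartileGroups <- function(tab) {
  n <- nrow(tab)
  if (n < 4) stop("quartile grouping needs at least 4 features")
  base <- n %/% 4
  rem <- n %% 4
  sizes <- rep(base, 4)
  extra <- c(1, 4, 2)[seq_len(rem)]
  sizes[extra] <- sizes[extra] + 1
  ord <- order(-tab$icc, tab$feature_name)
  lab <- character(n)
  lab[ord] <- rep(paste0("Q", 1:4), times = sizes)
  factor(lab, levels = paste0("Q", 1:4))
}

#' Threshold-based reliability signatures
#'
#' \code{high}: features with ICC strictly above 0.99; \code{low}: strictly
#' below 0.75; \code{all}: every feature. Boundary values 0.99 and 0.75 are
#' excluded from high/low respectively.
#'
#' @param tab data.frame with \code{feature_name} and \code{icc}.
#' @param highThreshold,lowThreshold signature cutoffs.
#' @return list of class \code{signatureSet} with character vectors
#'   \code{high}, \code{low}, \code{all}.
#' @export
thresholdSignatures <- function(tab, highThreshold = 0.99,
                                lowThreshold = 0.75) {
  out <- list(high = tab$feature_name[tab$icc > highThreshold],
              low = tab$feature_name[tab$icc < lowThreshold],
              all = tab$feature_name)
  if (!length(out$high))
    warning("high-ICC signature is empty at threshold ", highThreshold)
  if (!length(out$low))
    warning("low-ICC signature is empty at threshold ", lowThreshold)
  class(out) <- "signatureSet"
  out
}

#' Compare manual-rater and automatic-variant reliability per quartile
#'
#' Features are grouped into quartiles by the manual table's ICCs; within
#' each quartile the paired manual-vs-automatic ICC difference is tested
#' with the Wilcoxon signed-rank test.
#'
#' @param tManual,tAuto ICC tables from \code{\link{iccTable}} over the same
#'   feature set.
#' @param alpha significance level for the star annotation.
#' @return data.frame with 4 rows: quartile, n_features, median_manual,
#'   median_auto, median_difference, statistic, p_value, stars, exact.
#' @export
compareManualAuto <- function(tManual, tAuto, alpha = 0.05) {
  if (!setequal(tManual$feature_name, tAuto$feature_name))
    stop("manual and automatic tables must cover the same features")
  q <- tManual$quartile
  am <- tAuto$icc[match(tManual$feature_name, tAuto$feature_name)]
  rows <- lapply(paste0("Q", 1:4), function(qq) {
    sel <- q == qq
    mi <- tManual$icc[sel]
    ai <- am[sel]
    exact <- sum(sel) < 5
    if (all(mi == ai)) {
      stat <- NA_real_; p <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(mi, ai, paired = TRUE,
                                         exact = exact))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(quartile = qq, n_features = sum(sel),
               median_manual = median(mi), median_auto = median(ai),
               median_difference = median(mi - ai),
               statistic = stat, p_value = p,
               stars = significanceStars(p), exact = exact,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
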