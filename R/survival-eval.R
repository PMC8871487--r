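#' Stratified cross-validation folds for survival data
#'
#' Survival times are stratified into one-year intervals (at most 1 year,
#' 1-2, 2-3, more than 3 years; the 1-year boundary belongs to the first
#' interval) crossed with the event/censor indicator, giving up to 8 strata.
#' Each stratum's members are shuffled with the seed and dealt round-robin
#' across folds, with the starting fold rotated per stratum so remainders
#' spread evenly.
#'
#' @param records data.frame with patient_id, time_years, event.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for the shuffles.
#' @return list of class \code{cvPlan}: \code{fold} (integer per patient,
#'   named by patient_id), \code{strata} (factor), \code{nFolds}.
#' @export
stratifiedFolds <- function(records, nFolds = 5, seed = 1L) {
  n <- nrow(records)
  if (n < nFolds) stop("need at least as many patients as folds")
  interval <- cut(records$time_years, c(0, 1, 2, 3, Inf),
                  labels = c("<=1y", "1-2y", "2-3y", ">3y"), right = TRUE)
  strata <- interaction(interval, factor(records$event, levels = 0:1),
                        drop = FALSE)
  fold <- integer(n)
  set.seed(seed)
  levs <- levels(strata)
  for (si in seq_along(levs)) {
    idx <- which(strata == levs[si])
    if (!length(idx)) next
    if (length(idx) < nFolds)
      warning("stratum '", levs[si], "' has fewer members (",
              length(idx), ") than folds; distributing as evenly as possible")
    idx <- idx[sample.int(length(idx))]
    start <- (si - 1) %% nFolds
    fold[idx] <- ((seq_along(idx) - 1 + start) %% nFolds) + 1L
  }
  structure(list(fold = setNames(fold, records$patient_id),
                 strata = setNames(strata, records$patient_id),
                 nFolds = as.integer(nFolds)),
            class = "cvPlan")
}

#' Sequential forward feature selection by concordance
#'
#' Step one picks the feature whose raw values have the highest univariate
#' concordance index on the training data; each later step greedily adds the
#' candidate that maximizes the refitted Cox model's training concordance.
#' Selection stops when the best improvement falls below
#' \code{minImprovement} or \code{maxK} features are selected. Ties are
#' broken by feature name; constant features are skipped.
#'
#' @param X training feature matrix (patients x features).
#' @param time,event training outcome.
#' @param candidates character, the signature's feature names (columns of
#'   \code{X}).
#' @param maxK maximum number of selected features (default 5).
#' @param minImprovement minimum gain in training C to accept a feature
#'   (default 0.005).
#' @param penalty ridge penalty for the intermediate Cox fits.
#' @return character vector of selected features (in selection order).
#' @export
forwardSelect <- function(X, time, event, candidates = colnames(X),
                          maxK = 5, minImprovement = 0.005,
                          penalty = 1e-6) {
  stopifnot(length(candidates) >= 1)
  X <- as.matrix(X)[, candidates, drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    message("skipping ", sum(sds == 0), " constant feature(s)")
  cand <- sort(candidates[sds > 0])
  if (!length(cand)) stop("no non-constant candidate features")

  uniC <- vapply(cand, function(f)
    concordanceIndex(X[, f], time, event), numeric(1))
  best <- cand[which.max(uniC)]       # ties: first in name order
  selected <- best
  cand <- setdiff(cand, best)
  # baseline for the improvement rule: the fitted univariate model's C
  bestC <- tryCatch({
    fit1 <- fitCoxPH(X[, best, drop = FALSE], time, event,
                     penalty = penalty)
    concordanceIndex(predictRisk(fit1, X), time, event)
  }, error = function(e) max(uniC))

  while (length(selected) < maxK && length(cand)) {
    stepC <- vapply(cand, function(f) {
      fit <- tryCatch(
        fitCoxPH(X[, c(selected, f), drop = FALSE], time, event,
                 penalty = penalty),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      concordanceIndex(predictRisk(fit, X), time, event)
    }, numeric(1))
    if (all(is.na(stepC))) break
    k <- which.max(stepC)             # first max in name order
    if (is.na(stepC[k]) || stepC[k] - bestC < minImprovement) break
    selected <- c(selected, cand[k])
    bestC <- stepC[k]
    cand <- cand[-k]
  }
  selected
}

# Wide (patients x features) matrix for one segmentation id. Internal.
segmentationMatrix <- function(se, segId, patients = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- cd$segmentation_id == segId
  mat <- t(SummarizedExperiment::assay(se, "features")[, keep, drop = FALSE])
  rownames(mat) <- cd$patient_id[keep]
  if (!is.null(patients)) mat <- mat[patients, , drop = FALSE]
  mat
}

#' Evaluate one ICC signature across folds and segmentation variants
#'
#' Per fold, features are forward-selected and the Cox model fitted on the
#' training patients' first-manual-segmentation features; that fixed model
#' is then scored on the test fold once per segmentation (manual plus every
#' automatic variant), isolating segmentation-induced spread of the
#' concordance index. \code{refitPerVariant = TRUE} instead refits the model
#' on each variant's training features before scoring it.
#'
#' @param se feature \code{SummarizedExperiment}.
#' @param records survival data.frame (patient_id, time_years, event).
#' @param signature character vector of feature names (e.g. one element of
#'   \code{\link{thresholdSignatures}}).
#' @param cv a \code{cvPlan} from \code{\link{stratifiedFolds}}.
#' @param signatureName label stored in the result.
#' @param maxK,minImprovement,penalty forwarded to
#'   \code{\link{forwardSelect}} / \code{\link{fitCoxPH}}.
#' @param refitPerVariant logical (default FALSE).
#' @return list of class \code{cindexDistribution}: \code{signature},
#'   \code{values} (data.frame fold, segmentation_id, c_index),
#'   \code{mean}, \code{sd} (pooled over all values), \code{sdWithinFold}
#'   (root-mean within-fold variance: the spread over segmentation variants
#'   alone), \code{incomplete}, \code{selected} (features per fold).
#' @export
evaluateSignature <- function(se, records, signature, cv,
                              signatureName = "all", maxK = 5,
                              minImprovement = 0.005, penalty = 1e-6,
                              refitPerVariant = FALSE) {
  stopifnot(inherits(cv, "cvPlan"), length(signature) >= 1)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  # evaluated outlines: the reference manual segmentation plus every
  # automatic variant (additional manual raters feed reliability scoring
  # only)
  segIds <- unique(c("manual1",
                     cd$segmentation_id[cd$segmentation_type ==
                                          "automatic"]))
  patients <- intersect(records$patient_id, unique(cd$patient_id))
  records <- records[match(patients, records$patient_id), ]
  fold <- cv$fold[patients]

  # one wide (patients x features) matrix per segmentation, built once
  mat <- SummarizedExperiment::assay(se, "features")
  wide <- lapply(segIds, function(segId) {
    keep <- cd$segmentation_id == segId
    w <- t(mat[, keep, drop = FALSE])
    rownames(w) <- cd$patient_id[keep]
    w[patients, , drop = FALSE]
  })
  names(wide) <- segIds

  vals <- list()
  selectedPerFold <- list()
  incomplete <- FALSE
  for (k in seq_len(cv$nFolds)) {
    train <- patients[fold != k]
    test <- patients[fold == k]
    rtr <- records[match(train, records$patient_id), ]
    rte <- records[match(test, records$patient_id), ]
    Xtr <- wide[["manual1"]][train, signature, drop = FALSE]
    res <- tryCatch({
      sel <- forwardSelect(Xtr, rtr$time_years, rtr$event,
                           candidates = signature, maxK = maxK,
                           minImprovement = minImprovement,
                           penalty = penalty)
      fit <- fitCoxPH(Xtr[, sel, drop = FALSE], rtr$time_years, rtr$event,
                      penalty = penalty)
      list(sel = sel, fit = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("fold ", k, " skipped: ", conditionMessage(res))
      incomplete <- TRUE
      next
    }
    selectedPerFold[[k]] <- res$sel
    ci <- vapply(segIds, function(segId) {
      Xte <- wide[[segId]][test, , drop = FALSE]
      fit <- res$fit
      if (refitPerVariant && segId != "manual1") {
        Xtrv <- wide[[segId]][train, , drop = FALSE]
        fit <- tryCatch(
          fitCoxPH(Xtrv[, res$sel, drop = FALSE], rtr$time_years,
                   rtr$event, penalty = penalty),
          error = function(e) res$fit)
      }
      tryCatch(
        concordanceIndex(predictRisk(fit, Xte), rte$time_years, rte$event),
        error = function(e) NA_real_)
    }, numeric(1))
    vals[[length(vals) + 1]] <- data.frame(
      fold = k, segmentation_id = segIds, c_index = unname(ci),
      stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, vals)
  if (anyNA(values$c_index)) incomplete <- TRUE
  # pooled SD mixes fold-to-fold and segmentation-induced scatter; the
  # within-fold SD isolates the spread over segmentation variants
  withinVar <- tapply(values$c_index, values$fold, var)
  structure(list(signature = signatureName, values = values,
                 mean = mean(values$c_index, na.rm = TRUE),
                 sd = sd(values$c_index, na.rm = TRUE),
                 sdWithinFold = sqrt(mean(withinVar, na.rm = TRUE)),
                 incomplete = incomplete, selected = selectedPerFold),
            class = "cindexDistribution")
}

#' @export
print.cindexDistribution <- function(x, ...) {
  cat("C-index distribution [", x$signature, "]: ",
      nrow(x$values), " values, mean ", round(x$mean, 4),
      ", sd ", round(x$sd, 4),
      if (x$incomplete) " (incomplete)", "\n", sep = "")
  invisible(x)
}

#' Median split into risk groups with Kaplan-Meier summaries
#'
#' Risk scores are computed on the supplied features; patients with scores
#' strictly below the median form the low-risk group, scores at or above
#' the median the high-risk group (the boundary goes high because the
#' defining rule is "below the median" for low risk).
#'
#' @param model a \code{coxModel}.
#' @param X feature matrix for the evaluated patients.
#' @param records matching survival records.
#' @return list: \code{groups} (factor low/high named by patient),
#'   \code{medianScore}, \code{km} (a \code{survfit} object, or NULL when
#'   all scores are equal), \code{eventRates} per group.
#' @export
riskStratify <- function(model, X, records) {
  score <- predictRisk(model, X)
  med <- median(score)
  if (all(score == score[1])) {
    warning("all risk scores equal; single risk group")
    groups <- factor(rep("high", length(score)), levels = c("low", "high"))
    km <- NULL
  } else {
    groups <- factor(ifelse(score < med, "low", "high"),
                     levels = c("low", "high"))
    km <- survival::survfit(
      survival::Surv(records$time_years, records$event) ~ groups)
  }
  names(groups) <- records$patient_id
  structure(list(groups = groups, medianScore = med, km = km,
                 eventRates = tapply(records$event, groups, mean)),
            class = "riskStratification")
}
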