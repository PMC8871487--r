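# Statistical test battery used to compare C-index and ICC distributions:
# Friedman (a-priori across the three signatures), Wilcoxon signed-rank
# (paired location), Bartlett (variance), D'Agostino-Pearson (normality
# pre-check). All two-sided; significance is judged against an adjusted
# alpha (Bonferroni 0.05/2 for the two pairwise comparisons per modality).

testResult <- function(test, statistic, p, n, alphaAdjusted) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p), n = n,
                 alpha_adjusted = alphaAdjusted,
                 significant = !is.na(p) && p < alphaAdjusted,
                 stars = significanceStars(p)),
            class = "radstabTest")
}

#' @export
print.radstabTest <- function(x, ...) {
  cat(x$test, ": statistic ", signif(x$statistic, 5), ", p ",
      signif(x$p_value, 4), " (alpha ", x$alpha_adjusted, ") ",
      x$stars, "\n", sep = "")
  invisible(x)
}

#' Friedman rank test for matched groups
#'
#' @param m numeric matrix, blocks (rows) x groups (columns); k >= 3
#'   groups, n >= 2 blocks, complete.
#' @param alpha significance level recorded in the result.
#' @return a \code{radstabTest} (chi-square statistic, k-1 df).
#' @export
friedmanTest <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("Friedman test needs at least 3 matched groups")
  if (nrow(m) < 2) stop("Friedman test needs at least 2 blocks")
  if (anyNA(m)) stop("unequal block counts (missing cells)")
  ft <- friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {
    # every block fully tied (e.g. identical groups): no rank differences
    stat <- 0
    p <- 1
  }
  testResult("Friedman", stat, p, nrow(m), alpha)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original procedure); tied
#' absolute ranks are averaged. The exact null distribution is used for
#' small samples (full sign-pattern enumeration up to 15 nonzero
#' differences, the closed-form exact distribution up to 25 when there are
#' no ties), the normal approximation with continuity correction otherwise.
#' All differences zero gives p = 1 with a degeneracy flag.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alpha significance level recorded in the result.
#' @return a \code{radstabTest}; extra fields \code{degenerate} and
#'   \code{medianDifference}.
#' @export
wilcoxonSignedRank <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0) {
    out <- testResult("Wilcoxon signed-rank", NA_real_, 1, length(a), alpha)
    out$degenerate <- TRUE
    out$medianDifference <- 0
    return(out)
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (nz <= 15) {
    # exact permutation: enumerate all 2^nz sign patterns (valid with ties)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), nz)))
    Vnull <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(Vnull <= V), mean(Vnull >= V)))
    stat <- V
  } else if (!ties && nz <= 25) {
    wt <- wilcox.test(d, exact = TRUE)
    p <- wt$p.value
    stat <- unname(wt$statistic)
  } else {
    wt <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    stat <- unname(wt$statistic)
  }
  out <- testResult("Wilcoxon signed-rank", stat, p, nz, alpha)
  out$degenerate <- FALSE
  out$medianDifference <- median(d)
  out
}

#' Bartlett's test for homogeneity of variances
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha significance level recorded in the result.
#' @return a \code{radstabTest} (chi-square statistic, k-1 df).
#' @export
bartlettTest <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, function(g) length(g) < 2, logical(1))))
    stop("every group needs at least 2 observations")
  if (any(vapply(groups, function(g) var(g) == 0, logical(1))))
    stop("zero-variance group: Bartlett statistic undefined")
  bt <- bartlett.test(groups)
  testResult("Bartlett", bt$statistic, bt$p.value,
             sum(lengths(groups)), alpha)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) z-scores into K2 = z_s^2 + z_k^2, referred to a
#' chi-square with 2 df. Requires n >= 20 for the approximations to hold.
#'
#' @param x numeric sample (n >= 20, non-constant).
#' @param alpha significance level recorded in the result.
#' @return a \code{radstabTest}; extra fields \code{zSkewness},
#'   \code{zKurtosis}.
#' @export
dagostinoTest <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 20) stop("D'Agostino test requires n >= 20")
  if (var(x) == 0) stop("constant sample: normality test undefined")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alphaS <- sqrt(2 / (W2 - 1))
  zs <- delta * log(Y / alphaS + sqrt((Y / alphaS)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- zs^2 + zk^2
  out <- testResult("D'Agostino-Pearson", K2,
                    pchisq(K2, df = 2, lower.tail = FALSE), n, alpha)
  out$zSkewness <- zs
  out$zKurtosis <- zk
  out
}

#' Compare the three ICC-signature C-index distributions
#'
#' Runs the full battery: D'Agostino normality pre-check per signature
#' (motivating the rank-based paired test), the a-priori Friedman test
#' across high/all/low on the matched (fold, segmentation) values, paired
#' Wilcoxon signed-rank tests for high-vs-all and low-vs-all locations, and
#' Bartlett tests for their spreads. The two pairwise location comparisons
#' per modality are judged at the Bonferroni-adjusted alpha 0.05/2.
#'
#' @param high,all,low \code{cindexDistribution} objects from
#'   \code{\link{evaluateSignature}} (low may be NULL if the signature was
#'   empty).
#' @param alpha unadjusted significance level (default 0.05).
#' @param nComparisons Bonferroni divisor (default 2, the two pairwise
#'   mean comparisons per modality).
#' @return list of class \code{signatureComparison}: \code{tests} (named
#'   list of \code{radstabTest}), \code{table} (data.frame summary),
#'   \code{alphaAdjusted}.
#' @export
compareSignatures <- function(high, all, low = NULL, alpha = 0.05,
                              nComparisons = 2) {
  alphaAdj <- alpha / nComparisons
  dists <- list(high = high, all = all, low = low)
  dists <- dists[!vapply(dists, is.null, logical(1))]
  if (length(dists) < 2) stop("need at least two signature distributions")
  if (!"all" %in% names(dists)) stop("the 'all' signature is required")

  key <- function(d) paste(d$values$fold, d$values$segmentation_id)
  common <- Reduce(intersect, lapply(dists, key))
  aligned <- lapply(dists, function(d)
    d$values$c_index[match(common, key(d))])

  tests <- list()
  for (nm in names(aligned))
    tests[[paste0("normality_", nm)]] <- tryCatch(
      dagostinoTest(aligned[[nm]], alpha), error = function(e) NULL)
  if (length(aligned) == 3)
    tests$friedman <- friedmanTest(do.call(cbind, aligned), alpha)
  for (nm in setdiff(names(aligned), "all")) {
    tests[[paste0("wilcoxon_", nm, "_vs_all")]] <-
      wilcoxonSignedRank(aligned[[nm]], aligned$all, alphaAdj)
    tests[[paste0("bartlett_", nm, "_vs_all")]] <- tryCatch(
      bartlettTest(list(aligned[[nm]], aligned$all), alphaAdj),
      error = function(e) {
        warning("Bartlett ", nm, " vs all skipped: ", conditionMessage(e))
        NULL
      })
  }
  tests <- tests[!vapply(tests, is.null, logical(1))]
  table <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(comparison = nm, test = t$test, statistic = t$statistic,
               p_value = t$p_value, n = t$n,
               alpha_adjusted = t$alpha_adjusted,
               significant = t$significant, stars = t$stars,
               stringsAsFactors = FALSE)
  }))
  means <- vapply(aligned, mean, numeric(1))
  sds <- vapply(aligned, sd, numeric(1))
  structure(list(tests = tests, table = table, mean = means, sd = sds,
                 alphaAdjusted = alphaAdj),
            class = "signatureComparison")
}

#' @export
print.signatureComparison <- function(x, ...) {
  cat("Signature comparison (alpha_adjusted =", x$alphaAdjusted, ")\n")
  cat("  mean C:", paste(names(x$mean), round(x$mean, 4), collapse = ", "),
      "\n")
  cat("  SD C:  ", paste(names(x$sd), round(x$sd, 4), collapse = ", "),
      "\n")
  print(x$table[, c("comparison", "statistic", "p_value", "stars")],
        row.names = FALSE)
  invisible(x)
}
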