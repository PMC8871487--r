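fakeDist <- function(name, values, folds = 5) {
  nseg <- length(values) / folds
  structure(list(signature = name,
                 values = data.frame(
                   fold = rep(seq_len(folds), each = nseg),
                   segmentation_id = rep(sprintf("s%03d", seq_len(nseg)),
                                         folds),
                   c_index = values),
                 mean = mean(values), sd = sd(values),
                 sdWithinFold = NA, incomplete = FALSE, selected = list()),
            class = "cindexDistribution")
}

test_that("Friedman: identical groups give statistic 0, consistent ranking
           gives the closed-form chi-square", {
  m <- matrix(rnorm(10), 10, 3)[, c(1, 1, 1)]
  r <- friedmanTest(m)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  m2 <- matrix(rep(c(1, 2, 3), each = 10), 10, 3) + rnorm(30, sd = 0.01)
  m2 <- t(apply(m2, 1, sort))                   # consistent ordering
  r2 <- friedmanTest(m2)
  expect_equal(unname(r2$statistic), 20)        # 12n/(k(k+1)) * sum(...)
  expect_error(friedmanTest(matrix(1, 5, 2)), "3 matched groups")
})

test_that("Wilcoxon signed-rank handles identity, constant shifts and the
           exact tail", {
  a <- rnorm(12)
  r <- wilcoxonSignedRank(a, a)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)

  b <- a - 1                                     # a - b = +1 for all pairs
  r2 <- wilcoxonSignedRank(a, b)
  # exhaustive enumeration over all 2^12 sign patterns
  maxW <- 12 * 13 / 2
  tail <- 2 * (1 / 2^12)                         # only the all-plus pattern
  expect_equal(r2$p_value, tail, tolerance = 1e-12)
  expect_equal(unname(r2$statistic), maxW)
})

test_that("p-values shrink monotonically as a paired shift grows", {
  set.seed(4)
  a <- rnorm(30)
  ps <- vapply(c(0, 0.2, 0.5, 1, 2), function(delta)
    wilcoxonSignedRank(a + delta + rnorm(30, sd = 1e-6), a)$p_value,
    numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("Bartlett: equal variances give statistic 0, unequal are detected", {
  g <- rnorm(50)
  r <- bartlettTest(list(g, g + 10))             # identical variances
  expect_equal(unname(r$statistic), 0, tolerance = 1e-12)
  expect_error(bartlettTest(list(rep(1, 5), rnorm(5))), "zero-variance")

  set.seed(6)
  rej <- mean(replicate(200, {
    bartlettTest(list(rnorm(100, sd = 1), rnorm(100, sd = 2)))$p_value
  }) < 0.05)
  expect_gt(rej, 0.9)
})

test_that("D'Agostino-Pearson matches an independent reference", {
  set.seed(7)
  xs <- rnorm(100)
  r <- dagostinoTest(xs)
  # scipy.stats.normaltest / skewtest / kurtosistest on the same sample
  expect_equal(unname(r$statistic), 2.522810105655007, tolerance = 1e-10)
  expect_equal(r$p_value, 0.2832557574678398, tolerance = 1e-10)
  expect_equal(r$zSkewness, 1.581555457470667, tolerance = 1e-10)
  expect_equal(r$zKurtosis, 0.14660300337904597, tolerance = 1e-10)

  set.seed(9)
  ys <- rexp(60)
  r2 <- dagostinoTest(ys)
  expect_equal(unname(r2$statistic), 6.511720604883011, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.03854764376229279, tolerance = 1e-10)

  expect_error(dagostinoTest(rnorm(10)), "n >= 20")
  expect_error(dagostinoTest(rep(2, 30)), "constant")
})

test_that("normality checks have reasonable size and power", {
  set.seed(15)
  sizeRej <- mean(replicate(100, dagostinoTest(rnorm(500))$p_value < 0.05))
  expect_lte(sizeRej, 0.10)
  powerRej <- mean(replicate(100, dagostinoTest(rexp(500))$p_value < 0.05))
  expect_gte(powerRej, 0.95)
})

test_that("signature comparison runs the full battery at alpha 0.05/2", {
  set.seed(20)
  v <- runif(5 * 20, 0.4, 0.8)
  high <- fakeDist("high", v)
  all_ <- fakeDist("all", v)
  low <- fakeDist("low", v)
  cmpSame <- compareSignatures(high, all_, low)
  expect_equal(unname(cmpSame$tests$friedman$p_value), 1)
  wilcoxRows <- grepl("wilcoxon", cmpSame$table$comparison)
  expect_true(all(cmpSame$table$alpha_adjusted[wilcoxRows] == 0.025))
  expect_false(any(cmpSame$table$significant[wilcoxRows]))
  expect_equal(sum(wilcoxRows), 2)     # exactly two pairwise comparisons

  vh <- v + 0.05 + rnorm(100, sd = 0.002)
  vl <- 0.5 + (v - mean(v)) * 3
  cmp <- compareSignatures(fakeDist("high", vh), all_, fakeDist("low", vl))
  wHigh <- cmp$tests$wilcoxon_high_vs_all
  expect_lt(wHigh$p_value, 0.025)
  expect_gt(wHigh$medianDifference, 0)           # high above all
  bLow <- cmp$tests$bartlett_low_vs_all
  expect_lt(bLow$p_value, 0.025)
  expect_gt(cmp$sd[["low"]], cmp$sd[["all"]])
})
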