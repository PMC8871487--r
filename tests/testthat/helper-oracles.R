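# Independent brute-force oracles. Everything here is written with explicit
# loops, separately from the package's implementation paths.

# --- one-way ANOVA ICC(1) by explicit sum-of-squares loops ---
oracleIcc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(m[i, ]) - grand)^2
  ssw <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ssw <- ssw + (m[i, j] - mean(m[i, ]))^2
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# --- Harrell C by exhaustive pair enumeration ---
oracleCindex <- function(risk, time, event) {
  conc <- 0; comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# --- gray-level matrices by enumeration ---
oracleGlcmCounts <- function(lev, ng, dr, dc) {
  P <- matrix(0, ng, ng)
  nr <- nrow(lev); nc <- ncol(lev)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- lev[i, j]
    if (a == 0) next
    ii <- i + dr; jj <- j + dc
    if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
    b <- lev[ii, jj]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracleGlrlmCounts <- function(lev, ng, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  R <- matrix(0, ng, max(nr, nc))
  seen <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    g <- lev[i, j]
    if (g == 0 || seen[i, j]) next
    # walk backwards to confirm this is a run start
    pi <- i - dr; pj <- j - dc
    if (pi >= 1 && pi <= nr && pj >= 1 && pj <= nc && lev[pi, pj] == g)
      next
    len <- 0
    ii <- i; jj <- j
    while (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && lev[ii, jj] == g) {
      seen[ii, jj] <- TRUE
      len <- len + 1
      ii <- ii + dr; jj <- jj + dc
    }
    R[g, len] <- R[g, len] + 1
  }
  R
}

oracleGlszmCounts <- function(lev, ng) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    g <- lev[i, j]
    if (g == 0 || seen[i, j]) next
    stack <- list(c(i, j))
    seen[i, j] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            !seen[ii, jj] && lev[ii, jj] == g) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  maxs <- max(vapply(zones, `[`, numeric(1), 2))
  Z <- matrix(0, ng, maxs)
  for (z in zones) Z[z[1], z[2]] <- Z[z[1], z[2]] + 1
  Z
}

oracleGldmCounts <- function(lev, ng, alpha = 0) {
  nr <- nrow(lev); nc <- ncol(lev)
  D <- matrix(0, ng, 9)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    g <- lev[i, j]
    if (g == 0) next
    dep <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        h <- lev[ii, jj]
        if (h != 0 && abs(h - g) <= alpha) dep <- dep + 1
      }
    }
    D[g, dep + 1] <- D[g, dep + 1] + 1
  }
  D
}

# naive feature formulas from a count matrix, explicit double loops
oracleGlcmFeatures <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  je <- 0; jent <- 0; con <- 0; dis <- 0; idm <- 0; idf <- 0
  cs <- 0; cp <- 0; sij <- 0
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + p[i, j]
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  s2 <- 0
  for (i in 1:ng) s2 <- s2 + (i - mu)^2 * px[i]
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    if (v > 0) jent <- jent - v * log2(v)
    je <- je + v^2
    con <- con + (i - j)^2 * v
    dis <- dis + abs(i - j) * v
    idm <- idm + v / (1 + (i - j)^2)
    idf <- idf + v / (1 + abs(i - j))
    cs <- cs + (i + j - 2 * mu)^3 * v
    cp <- cp + (i + j - 2 * mu)^4 * v
    sij <- sij + i * j * v
  }
  corr <- if (s2 > 0) (sij - mu^2) / s2 else 1
  c(JointEnergy = je, JointEntropy = jent, Contrast = con,
    Dissimilarity = dis, InverseDifferenceMoment = idm,
    InverseDifference = idf, Correlation = corr, ClusterShade = cs,
    ClusterProminence = cp)
}

oracleGlrlmFeatures <- function(R, nPixels) {
  nr <- sum(R)
  ng <- nrow(R); mr <- ncol(R)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0; rent <- 0
  gsum <- numeric(ng); rsum <- numeric(mr)
  for (i in 1:ng) for (j in 1:mr) {
    v <- R[i, j] / nr
    sre <- sre + v / j^2
    lre <- lre + v * j^2
    lgl <- lgl + v / i^2
    hgl <- hgl + v * i^2
    if (v > 0) rent <- rent - v * log2(v)
    gsum[i] <- gsum[i] + R[i, j]
    rsum[j] <- rsum[j] + R[i, j]
  }
  c(ShortRunEmphasis = sre, LongRunEmphasis = lre,
    GrayLevelNonUniformity = sum(gsum^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gsum^2) / nr^2,
    RunLengthNonUniformity = sum(rsum^2) / nr,
    RunLengthNonUniformityNormalized = sum(rsum^2) / nr^2,
    RunPercentage = nr / nPixels,
    LowGrayLevelRunEmphasis = lgl, HighGrayLevelRunEmphasis = hgl,
    RunEntropy = rent)
}

oracleGlszmFeatures <- function(Z, nPixels) {
  nz <- sum(Z)
  ng <- nrow(Z); ms <- ncol(Z)
  sae <- 0; lae <- 0; lgl <- 0; hgl <- 0; zent <- 0
  gsum <- numeric(ng); ssum <- numeric(ms)
  for (i in 1:ng) for (s in 1:ms) {
    v <- Z[i, s] / nz
    sae <- sae + v / s^2
    lae <- lae + v * s^2
    lgl <- lgl + v / i^2
    hgl <- hgl + v * i^2
    if (v > 0) zent <- zent - v * log2(v)
    gsum[i] <- gsum[i] + Z[i, s]
    ssum[s] <- ssum[s] + Z[i, s]
  }
  c(SmallAreaEmphasis = sae, LargeAreaEmphasis = lae,
    GrayLevelNonUniformity = sum(gsum^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gsum^2) / nz^2,
    SizeZoneNonUniformity = sum(ssum^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ssum^2) / nz^2,
    ZonePercentage = nz / nPixels, ZoneEntropy = zent,
    LowGrayLevelZoneEmphasis = lgl, HighGrayLevelZoneEmphasis = hgl)
}

oracleGldmFeatures <- function(D) {
  nd <- sum(D)
  ng <- nrow(D); mj <- ncol(D)
  sde <- 0; lde <- 0; lgl <- 0; hgl <- 0; dent <- 0; muj <- 0
  gsum <- numeric(ng); jsum <- numeric(mj)
  for (i in 1:ng) for (j in 1:mj) {
    v <- D[i, j] / nd
    sde <- sde + v / j^2
    lde <- lde + v * j^2
    lgl <- lgl + v / i^2
    hgl <- hgl + v * i^2
    if (v > 0) dent <- dent - v * log2(v)
    muj <- muj + j * v
    gsum[i] <- gsum[i] + D[i, j]
    jsum[j] <- jsum[j] + D[i, j]
  }
  dvar <- 0
  for (j in 1:mj) dvar <- dvar + (j - muj)^2 * jsum[j] / nd
  c(SmallDependenceEmphasis = sde, LargeDependenceEmphasis = lde,
    GrayLevelNonUniformity = sum(gsum^2) / nd,
    DependenceNonUniformity = sum(jsum^2) / nd,
    DependenceNonUniformityNormalized = sum(jsum^2) / nd^2,
    DependenceEntropy = dent, DependenceVariance = dvar,
    LowGrayLevelEmphasis = lgl, HighGrayLevelEmphasis = hgl)
}

# random level matrix with 0 border-of-mask cells possible
randomLevels <- function(nr = 8, nc = 8, ng = 4, maskProb = 0.85) {
  lev <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  lev[matrix(runif(nr * nc) > maskProb, nr, nc)] <- 0L
  if (all(lev == 0)) lev[1, 1] <- 1L
  storage.mode(lev) <- "integer"
  attr(lev, "nGray") <- as.integer(ng)
  lev
}

# small textured disk case for perturbation tests
diskCase <- function(radius = 10, imageSize = 48, seed = 1, sigma = 1,
                     irregularity = 0) {
  makePhantom(phantomSpec(imageSize = imageSize, axes = c(radius, radius),
                          irregularity = irregularity,
                          boundarySigma = sigma, seed = seed))
}

# tiny cohort used by several reliability/survival tests
tinyCohort <- function(nPatients = 10, nVariants = 12, masterSeed = 1,
                       amplitude = 2) {
  makeCohort(nPatients,
             phantom = phantomSpec(imageSize = 64),
             perturb = perturbationSpec(nVariants = nVariants,
                                        amplitude = amplitude,
                                        noiseCorrelation = 2),
             variation = cohortVariation(axesFactor = c(0.6, 1.4)),
             masterSeed = masterSeed)
}

tinyFeatureConfig <- function() featureConfig(wavelet = FALSE)
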