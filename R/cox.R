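#' Harrell's concordance index
#'
#' A pair (i, j) is comparable when \code{time[i] < time[j]} and the earlier
#' patient's event was observed. A comparable pair is concordant when the
#' earlier-failing patient has the higher risk score; tied risk scores count
#' one half. Returns concordant weight divided by the number of comparable
#' pairs.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time follow-up times.
#' @param event event indicators (1 observed, 0 censored).
#' @return concordance in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    m <- sum(later)
    if (!m) next
    comp <- comp + m
    conc <- conc + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0)
    stop("no comparable pairs (all times tied or all events censored)")
  conc / comp
}

# Breslow log partial likelihood, score and information for standardized X.
# Risk sets are cumulative heads of the time-descending ordering; cumulative
# first and second weighted moments make each event's contribution O(p^2).
coxDerivatives <- function(Z, time, event, beta, penalty) {
  ord <- order(-time)
  Zo <- Z[ord, , drop = FALSE]
  to <- time[ord]
  eo <- event[ord]
  lp <- as.vector(Zo %*% beta)
  shift <- max(lp)             # stabilises exp without changing the PL
  w <- exp(lp - shift)
  p <- ncol(Z)
  S0 <- cumsum(w)
  S1 <- apply(Zo * w, 2, cumsum)
  if (p == 1) S1 <- matrix(S1, ncol = 1)
  S2 <- array(0, c(length(w), p, p))
  for (a in seq_len(p)) for (b in a:p) {
    cs <- cumsum(w * Zo[, a] * Zo[, b])
    S2[, a, b] <- cs
    S2[, b, a] <- cs
  }
  # the risk set of an event at time t includes every subject with time >= t:
  # advance the cumulative index to the end of each tie group
  lastOfTie <- ave(seq_along(to), to, FUN = max)
  ev <- which(eo == 1)
  r <- lastOfTie[ev]
  # log S0_true = log S0 + shift, and lp_true = lp, so each event term is
  # lp[ev] - (log(S0[r]) + shift)
  ll <- sum(lp[ev]) - length(ev) * shift - sum(log(S0[r]))
  grad <- colSums(Zo[ev, , drop = FALSE]) -
    colSums(S1[r, , drop = FALSE] / S0[r])
  info <- matrix(0, p, p)
  for (ru in unique(r)) {
    cnt <- sum(r == ru)
    s1n <- S1[ru, ] / S0[ru]
    info <- info + cnt * (S2[ru, , ] / S0[ru] - tcrossprod(s1n))
  }
  list(ll = ll - 0.5 * penalty * sum(beta^2),
       grad = grad - penalty * beta,
       info = info + diag(penalty, p))
}

#' Fit a Cox proportional-hazards model by Newton iterations
#'
#' Maximizes the Breslow partial likelihood with a small ridge penalty for
#' numerical stability, using Newton steps with step-halving so the
#' (penalized) log partial likelihood never decreases. Features are
#' standardized internally; the centering/scaling parameters are stored on
#' the model and applied by \code{\link{predictRisk}}.
#'
#' @param X numeric matrix or data.frame, patients x features.
#' @param time,event survival outcome.
#' @param penalty ridge penalty on the standardized coefficients
#'   (default 1e-6).
#' @param maxit maximum Newton iterations.
#' @param tol convergence threshold on \code{max |score| / n}.
#' @return list of class \code{coxModel}: \code{features}, \code{coef}
#'   (log hazard ratios per SD), \code{center}, \code{scale},
#'   \code{logLikTrace}, \code{converged}, \code{iterations}.
#' @export
fitCoxPH <- function(X, time, event, penalty = 1e-6, maxit = 100,
                     tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(time), n == length(event))
  if (sum(event) < 1) stop("no observed events")
  if (n < 2 * ncol(X))
    warning("fewer than 2 patients per feature; fit may be unstable")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  bad <- scl == 0
  scl[bad] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  p <- ncol(Z)
  beta <- numeric(p)
  d <- coxDerivatives(Z, time, event, beta, penalty)
  trace <- d$ll
  converged <- FALSE
  iter <- 0
  while (iter < maxit) {
    iter <- iter + 1
    step <- tryCatch(solve(d$info, d$grad), error = function(e) NULL)
    if (is.null(step))
      stop("singular information matrix; offending feature likely '",
           colnames(X)[which.max(abs(d$grad))], "'")
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      dc <- coxDerivatives(Z, time, event, cand, penalty)
      if (dc$ll >= d$ll - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- cand
    d <- dc
    trace <- c(trace, d$ll)
    if (max(abs(d$grad)) / n < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(d$grad)) / n > 1e-4) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop("Cox fit did not converge (possible separation in feature '",
         worst, "')")
  }
  if (max(abs(beta)) > 50)
    stop("divergent coefficient (separation) in feature '",
         colnames(X)[which.max(abs(beta))], "'")
  structure(list(features = colnames(X), coef = setNames(beta, colnames(X)),
                 center = ctr, scale = scl, logLikTrace = trace,
                 converged = converged, iterations = iter),
            class = "coxModel")
}

#' Linear risk score of a fitted Cox model
#'
#' @param model a \code{coxModel} from \code{\link{fitCoxPH}}.
#' @param X feature matrix/data.frame containing the model's features.
#' @return numeric risk scores (linear predictor on the training
#'   standardization).
#' @export
predictRisk <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.vector(Z %*% model$coef)
}

#' @export
print.coxModel <- function(x, ...) {
  cat("Cox proportional-hazards model (", length(x$features),
      " features, ", x$iterations, " Newton iterations",
      if (x$converged) ", converged" else ", NOT converged", ")\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}
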