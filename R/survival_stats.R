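# Survival statistics used throughout the pipeline: the product-limit
# estimator, the two-group log-rank test, Harrell's concordance index,
# a Newton-Raphson Cox regression engine with Breslow tie handling, and
# Benjamini-Hochberg adjustment.

#' Kaplan-Meier product-limit curve
#'
#' @param surv a [survival_table()]
#' @return A list of class `km_curve`: `times` (distinct event times,
#'   increasing), `survival` (product-limit estimate just after each
#'   event time), `at_risk`, `events`. A cohort with no events yields
#'   zero-length vectors (the curve is flat at 1).
#' @export
km_curve <- function(surv) {
  stopifnot(nrow(surv) >= 1)
  et <- sort(unique(surv$time[surv$event == 1]))
  n_risk <- integer(length(et))
  d <- integer(length(et))
  s <- numeric(length(et))
  cum <- 1
  for (k in seq_along(et)) {
    n_risk[k] <- sum(surv$time >= et[k])
    d[k] <- sum(surv$time == et[k] & surv$event == 1)
    cum <- cum * (1 - d[k] / n_risk[k])
    s[k] <- cum
  }
  structure(list(times = et, survival = s, at_risk = n_risk, events = d),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Observed-minus-expected event counts with hypergeometric variance,
#' summed over distinct event times; the chi-square statistic has one
#' degree of freedom. Also returns the signed standardized statistic
#' `z = (O1 - E1) / sqrt(V)` used for maximally selected cutpoints.
#'
#' @param surv a [survival_table()]
#' @param groups binary (0/1 or logical) group labels, one per row
#' @return A list of class `logrank_result`: `statistic`, `p`, `z`,
#'   `observed`, `expected` (each for group 1).
#' @export
logrank_test <- function(surv, groups) {
  g <- as.integer(as.logical(groups))
  if (length(g) != nrow(surv))
    stop("input error: one group label per sample required")
  if (length(unique(g)) < 2)
    stop("input error: both groups must be non-empty")
  if (sum(surv$event) < 1)
    stop("input error: at least one event required")
  et <- sort(unique(surv$time[surv$event == 1]))
  O1 <- E1 <- V <- 0
  for (tk in et) {
    at <- surv$time >= tk
    n <- sum(at)
    n1 <- sum(at & g == 1)
    dk <- sum(surv$time == tk & surv$event == 1)
    d1 <- sum(surv$time == tk & surv$event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + dk * n1 / n
    if (n > 1)
      V <- V + dk * (n1 / n) * (1 - n1 / n) * (n - dk) / (n - 1)
  }
  if (V <= 0) {
    stat <- 0; z <- 0; p <- 1
  } else {
    z <- (O1 - E1) / sqrt(V)
    stat <- z^2
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p = p, z = z, observed = O1, expected = E1),
            class = "logrank_result")
}

#' Harrell's concordance index
#'
#' A pair of subjects is comparable when the subject with the shorter
#' observed time had an event (including a time tie where one subject
#' had the event and the other was censored, in which case the censored
#' subject is known to have survived at least as long). Tied event
#' times with both events are incomparable, following Harrell's
#' original rule. A concordant pair is one where the higher risk score
#' belongs to the shorter survival; ties in score count one half.
#'
#' @param scores numeric risk scores (higher = predicted worse outcome)
#' @param surv a [survival_table()] of equal length
#' @return A list of class `concordance_result`: `cindex`, `concordant`,
#'   `discordant`, `tied_risk`, `comparable_pairs`.
#' @export
concordance_index <- function(scores, surv) {
  n <- nrow(surv)
  if (length(scores) != n)
    stop("input error: scores and survival table lengths differ")
  tm <- surv$time; ev <- surv$event
  conc <- disc <- ties <- 0L
  for (i in seq_len(n)) {
    if (ev[i] != 1) next
    # subject i failed; comparable with anyone observed strictly longer,
    # or equally long but censored
    j <- which(tm > tm[i] | (tm == tm[i] & ev == 0))
    if (!length(j)) next
    di <- scores[i] - scores[j]
    conc <- conc + sum(di > 0)
    disc <- disc + sum(di < 0)
    ties <- ties + sum(di == 0)
  }
  total <- conc + disc + ties
  if (total == 0) stop("estimation error: no comparable pairs")
  structure(list(cindex = (conc + 0.5 * ties) / total,
                 concordant = conc, discordant = disc,
                 tied_risk = ties, comparable_pairs = total),
            class = "concordance_result")
}

# Breslow partial log-likelihood, gradient and information for
# coefficients beta given covariates X (n x p). Internal workhorse
# shared by cox_fit and the gene screen.
.cox_partial <- function(beta, X, tm, ev) {
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)  # stabilize exp
  w <- exp(eta)
  et <- sort(unique(tm[ev == 1]))
  ll <- 0
  grad <- numeric(ncol(X))
  info <- matrix(0, ncol(X), ncol(X))
  for (tk in et) {
    risk <- tm >= tk
    dead <- tm == tk & ev == 1
    dk <- sum(dead)
    sw <- sum(w[risk])
    xw <- colSums(X[risk, , drop = FALSE] * w[risk])
    xbar <- xw / sw
    xxw <- crossprod(X[risk, , drop = FALSE] * sqrt(w[risk]))
    ll <- ll + sum(eta[dead]) - dk * log(sw)
    grad <- grad + colSums(X[dead, , drop = FALSE]) - dk * xbar
    info <- info + dk * (xxw / sw - tcrossprod(xbar))
  }
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Newton-Raphson maximization of the Breslow partial likelihood with
#' step-halving; convergence when the coefficient change falls below
#' `tol` (default 1e-8) or after `max_iter` iterations. Standard
#' errors come from the inverse observed information; Wald p-values
#' and 95% hazard-ratio intervals are reported per covariate.
#'
#' @param X covariate matrix (n x p) or vector
#' @param surv a [survival_table()]
#' @param tol,max_iter Newton-Raphson controls
#' @return A list of class `cox_fit`: `coef`, `se`, `hr`, `hr_lower`,
#'   `hr_upper`, `wald_p`, `loglik`, `converged`, `flagged` (per-
#'   covariate flag for degenerate/non-identifiable columns).
#' @export
cox_fit <- function(X, surv, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  tm <- surv$time; ev <- surv$event
  if (nrow(X) != length(tm))
    stop("input error: covariate rows must match survival rows")
  if (sum(ev) < 2) stop("estimation error: at least two events required")
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  flagged <- sds == 0
  if (all(flagged)) {
    return(structure(list(coef = rep(0, p), se = rep(NA_real_, p),
                          hr = rep(1, p), hr_lower = rep(NA_real_, p),
                          hr_upper = rep(NA_real_, p), wald_p = rep(1, p),
                          loglik = NA_real_, converged = TRUE,
                          flagged = flagged),
                     class = "cox_fit"))
  }
  use <- which(!flagged)
  Xu <- X[, use, drop = FALSE]
  beta <- numeric(length(use))
  ok <- FALSE
  pl <- .cox_partial(beta, Xu, tm, ev)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(pl$info, pl$grad), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      plc <- .cox_partial(cand, Xu, tm, ev)
      if (is.finite(plc$ll) && plc$ll >= pl$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    moved <- max(abs(lambda * step))
    beta <- beta + lambda * step
    pl <- plc
    if (moved < tol) { ok <- TRUE; break }
  }
  se <- rep(NA_real_, length(use))
  covb <- tryCatch(solve(pl$info), error = function(e) NULL)
  if (!is.null(covb)) se <- sqrt(pmax(diag(as.matrix(covb)), 0))
  coef <- se_full <- rep(NA_real_, p)
  coef[use] <- beta
  coef[flagged] <- 0
  se_full[use] <- se
  z <- coef / se_full
  wald_p <- 2 * stats::pnorm(-abs(z))
  wald_p[flagged] <- 1
  structure(list(coef = coef, se = se_full, hr = exp(coef),
                 hr_lower = exp(coef - 1.96 * se_full),
                 hr_upper = exp(coef + 1.96 * se_full),
                 wald_p = wald_p, loglik = pl$ll,
                 converged = ok, flagged = flagged),
            class = "cox_fit")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return Adjusted p-values (same length/order).
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
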