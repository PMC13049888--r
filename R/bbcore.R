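# Beta-binomial regression kernel shared by all scans.
#
# Parameterization: mean mu and intraclass correlation phi, i.e. the mixing
# distribution is Beta(mu * (1 - phi) / phi, (1 - mu) * (1 - phi) / phi).
# phi = 0 is the binomial limit and is handled exactly.

#' Beta-binomial log-likelihood
#'
#' Log probability of observing `meth` methylated reads out of `total` under
#' a beta-binomial with mean `mu` and intraclass-correlation dispersion
#' `phi`. With `phi = 0` this is exactly the binomial log-pmf. All arguments
#' are recycled to a common length and the summed log-likelihood is returned.
#'
#' @param meth Methylated read counts (non-negative integers).
#' @param total Total read counts; `total = 0` contributes 0 (log of 1).
#' @param mu Mean methylation probability, strictly inside (0, 1).
#' @param phi Dispersion (intraclass correlation), in `[0, 1)`.
#' @return Summed log-likelihood (scalar).
#' @examples
#' betabinom_loglik(3, 10, 0.3, 0)   # equals dbinom(3, 10, 0.3, log = TRUE)
#' betabinom_loglik(3, 10, 0.3, 0.2) # heavier-tailed than the binomial
#' @export
betabinom_loglik <- function(meth, total, mu, phi) {
  .check_counts(meth, total)
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop("'mu' must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1)) {
    stop("'phi' must be in [0, 1)", call. = FALSE)
  }
  sum(.bb_logpmf(meth, total, mu, phi))
}

# Vectorized log-pmf, no validation (internal hot path).
.bb_logpmf <- function(meth, total, mu, phi) {
  n <- max(length(meth), length(total), length(mu), length(phi))
  meth <- rep_len(meth, n); total <- rep_len(total, n)
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  z <- total == 0
  # below ~1e-8 the lbeta differences lose all precision; the binomial limit
  # is exact there (and at phi = 0 by definition)
  bin <- !z & phi < 1e-8
  bb <- !z & phi >= 1e-8
  if (any(bin)) {
    out[bin] <- dbinom(meth[bin], total[bin], mu[bin], log = TRUE)
  }
  if (any(bb)) {
    r <- (1 - phi[bb]) / phi[bb]
    a <- mu[bb] * r
    b <- (1 - mu[bb]) * r
    out[bb] <- lchoose(total[bb], meth[bb]) +
      lbeta(meth[bb] + a, total[bb] - meth[bb] + b) - lbeta(a, b)
  }
  out
}

#' Beta-binomial pmf
#'
#' @inheritParams betabinom_loglik
#' @param log Return log probabilities?
#' @return Vector of (log-)probabilities, one per observation.
#' @export
dbetabinom <- function(meth, total, mu, phi, log = FALSE) {
  .check_counts(meth, total)
  lp <- .bb_logpmf(meth, total, mu, phi)
  if (log) lp else exp(lp)
}

.MU_EPS <- 1e-9

# Negative log-likelihood for the regression model; par = c(beta, eta) with
# phi = plogis(eta). Returns a large finite value on numerical trouble so
# optim can back off.
.bb_negll <- function(par, X, meth, total) {
  p <- ncol(X)
  mu <- plogis(drop(X %*% par[seq_len(p)]))
  mu <- pmin(pmax(mu, .MU_EPS), 1 - .MU_EPS)
  phi <- plogis(par[p + 1L])
  ll <- sum(.bb_logpmf(meth, total, mu, phi))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a beta-binomial regression on the logit scale
#'
#' Maximum-likelihood fit of methylated counts out of total counts against a
#' design matrix, with a logit link for the mean and a single per-site
#' dispersion. Returns an object of class `"bbfit"` with `print`, `summary`,
#' `coef`, `logLik`, `vcov` and `fitted` methods. Wald z-tests are reported
#' per coefficient.
#'
#' Rows with `total = 0` are dropped before fitting (they carry no
#' information). A rank-deficient design is an error; non-convergence is
#' reported honestly through the `converged` flag, never silently.
#'
#' @param meth,total Count vectors, `0 <= meth <= total`.
#' @param X Design matrix (must include an intercept column).
#' @param start Optional starting coefficients (logit scale).
#' @param phi_start Dispersion starting values to try (best fit kept).
#' @param se Compute standard errors from the observed information? Set to
#'   `FALSE` to skip the Hessian (e.g. when only the likelihood is needed).
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @return A `bbfit` object: list with elements `coefficients`, `se`, `z`,
#'   `p.value`, `phi`, `logLik`, `converged`, `n_used`, `X`, `meth`, `total`.
#' @export
betabinom_glm <- function(meth, total, X, start = NULL,
                          phi_start = c(0.01, 0.15), se = TRUE,
                          reltol = 1e-9) {
  .check_counts(meth, total)
  X <- as.matrix(X)
  if (nrow(X) != length(meth)) {
    stop("design matrix rows must match the count vectors", call. = FALSE)
  }
  keep <- total > 0
  if (!any(keep)) stop("all totals are zero: no data to fit", call. = FALSE)
  meth <- meth[keep]; total <- total[keep]
  Xk <- X[keep, , drop = FALSE]
  p <- ncol(Xk)
  if (qr(Xk)$rank < p) {
    stop("design matrix is rank deficient", call. = FALSE)
  }

  if (is.null(start)) {
    start <- tryCatch(
      suppressWarnings(stats::glm.fit(Xk, cbind(meth, total - meth),
                                      family = stats::binomial())$coefficients),
      error = function(e) rep(0, p))
    start[!is.finite(start)] <- 0
    start <- pmin(pmax(start, -10), 10)
  }

  best <- NULL
  for (ph in phi_start) {
    fit <- tryCatch(
      stats::optim(c(start, qlogis(ph)), .bb_negll, X = Xk, meth = meth,
                   total = total, method = "BFGS",
                   control = list(maxit = 300, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("beta-binomial optimization failed", call. = FALSE)

  beta <- best$par[seq_len(p)]
  phi <- plogis(best$par[p + 1L])
  converged <- best$convergence == 0
  se_vec <- rep(NA_real_, p)
  vc <- NULL
  if (se) {
    H <- tryCatch(
      stats::optimHess(best$par, .bb_negll, X = Xk, meth = meth,
                       total = total),
      error = function(e) NULL)
    vc_full <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
               else NULL
    if (!is.null(vc_full) && all(is.finite(diag(vc_full))) &&
        all(diag(vc_full)[seq_len(p)] > 0)) {
      vc <- vc_full[seq_len(p), seq_len(p), drop = FALSE]
      se_vec <- sqrt(diag(vc))
    } else {
      converged <- FALSE
    }
  }
  z <- beta / se_vec
  pv <- 2 * pnorm(-abs(z))
  nm <- colnames(Xk)
  if (is.null(nm)) nm <- paste0("b", seq_len(p) - 1L)
  names(beta) <- names(se_vec) <- names(z) <- names(pv) <- nm
  if (!is.null(vc)) dimnames(vc) <- list(nm, nm)

  structure(list(coefficients = beta, se = se_vec, z = z, p.value = pv,
                 phi = phi, logLik = -best$value, converged = converged,
                 n_used = length(meth), X = Xk, meth = meth, total = total,
                 vcov = vc),
            class = "bbfit")
}

#' @export
print.bbfit <- function(x, ...) {
  cat("Beta-binomial regression (logit link)\n")
  cat(sprintf("  n = %d, phi = %.4g, logLik = %.3f, converged = %s\n",
              x$n_used, x$phi, x$logLik, x$converged))
  print(round(cbind(Estimate = x$coefficients, `Std.Err` = x$se,
                    z = x$z, `Pr(>|z|)` = x$p.value), 4))
  invisible(x)
}

#' @export
summary.bbfit <- function(object, ...) {
  out <- list(
    coefficients = cbind(Estimate = object$coefficients,
                         `Std. Error` = object$se, `z value` = object$z,
                         `Pr(>|z|)` = object$p.value),
    phi = object$phi, logLik = object$logLik,
    converged = object$converged, n_used = object$n_used)
  class(out) <- "summary.bbfit"
  out
}

#' @export
print.summary.bbfit <- function(x, ...) {
  cat("Beta-binomial regression (logit link)\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nDispersion (intraclass correlation) phi: %.4g\n", x$phi))
  cat(sprintf("Log-likelihood: %.3f on %d observations; converged: %s\n",
              x$logLik, x$n_used, x$converged))
  invisible(x)
}

#' @export
coef.bbfit <- function(object, ...) object$coefficients

#' @export
logLik.bbfit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' @export
vcov.bbfit <- function(object, ...) object$vcov

#' @export
fitted.bbfit <- function(object, ...) {
  plogis(drop(object$X %*% object$coefficients))
}

#' Likelihood-ratio test between nested beta-binomial fits
#'
#' @param fit_null,fit_alt `bbfit` objects, null nested in alternative.
#' @param df Degrees of freedom of the comparison.
#' @param tol Tolerance for a (numerically) lower alternative likelihood.
#' @return p-value from the chi-square reference distribution; the statistic
#'   is floored at 0.
#' @export
lrt <- function(fit_null, fit_alt, df, tol = 1e-6) {
  if (!fit_null$converged || !fit_alt$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  stat <- 2 * (fit_alt$logLik - fit_null$logLik)
  if (stat < -tol) {
    stop("alternative log-likelihood below null: optimization failure",
         call. = FALSE)
  }
  stat <- max(stat, 0)
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Empirical q-values calibrated against a permutation null
#'
#' For a rejection threshold t the false discovery rate is estimated as
#' `pi0 * (#\{p_perm <= t\} / n_permutations) / max(1, #\{p_obs <= t\})`, and
#' the q-value of site i is the minimum estimated FDR over thresholds
#' `t >= p_i` (hence monotone non-decreasing in p). The null proportion pi0
#' is estimated with the single-lambda rule `#\{p_obs > 0.5\} / (0.5 * m)`,
#' capped at 1.
#'
#' @param p_observed Observed p-values.
#' @param p_permuted Pooled p-values across all permutations.
#' @param n_permutations Number of permutations contributing to the pool.
#' @param lambda Cutoff for the pi0 estimator.
#' @return List with `qvalues` (aligned to `p_observed`) and `pi0`.
#' @export
empirical_qvalues <- function(p_observed, p_permuted, n_permutations,
                              lambda = 0.5) {
  if (length(p_permuted) == 0) {
    stop("empty permutation pool", call. = FALSE)
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  m <- length(p_observed)
  pi0 <- min(1, sum(p_observed > lambda) / ((1 - lambda) * m))
  ord <- order(p_observed)
  ps <- p_observed[ord]
  perm_sorted <- sort(p_permuted)
  # at threshold t = ps[i]: counts of perm and obs p-values <= t
  n_perm_le <- findInterval(ps, perm_sorted)
  n_obs_le <- seq_len(m)  # ties handled below via cummin from the right
  # for tied observed p-values use the largest rank
  n_obs_le <- vapply(seq_len(m), function(i) {
    if (i < m && ps[i + 1] == ps[i]) NA_real_ else i
  }, numeric(1))
  last <- m
  for (i in rev(seq_len(m))) {
    if (is.na(n_obs_le[i])) n_obs_le[i] <- last else last <- n_obs_le[i]
  }
  fdr <- pi0 * (n_perm_le / n_permutations) / pmax(1, n_obs_le)
  q_sorted <- rev(cummin(rev(pmin(fdr, 1))))
  q <- numeric(m)
  q[ord] <- q_sorted
  list(qvalues = q, pi0 = pi0)
}
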