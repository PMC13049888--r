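# Per-CpG scan for local- and global-ancestry effects on DNA methylation.

#' Site filters for the ancestry scan
#'
#' Retains CpG sites whose mean methylation (mean over individuals of the
#' per-individual methylated/total ratio) lies in `[0.10, 0.90]` and where
#' each local-ancestry state (dosage 0, 1, 2) is represented by at least
#' `min_per_state` individuals.
#'
#' @param counts A `meth_counts` object (or list with `meth`/`total`
#'   matrices, CpGs x individuals).
#' @param panel An `ancestry_panel`; its `dosage` rows for CpG loci must
#'   align with the rows of `counts`.
#' @param mean_range Inclusive mean-methylation bounds.
#' @param min_per_state Minimum individuals per ancestry state.
#' @return Integer vector of retained site (row) indices, with attributes
#'   `mean_methylation` and `n_per_state` for all sites.
#' @export
filter_sites <- function(counts, panel, mean_range = c(0.10, 0.90),
                         min_per_state = 10) {
  dosage <- .cpg_dosage(panel, nrow(counts$meth))
  if (ncol(counts$meth) != ncol(dosage)) {
    stop("counts and ancestry panel share no aligned individuals",
         call. = FALSE)
  }
  m <- nrow(counts$meth)
  mean_meth <- vapply(seq_len(m), function(j)
    .site_mean_methylation(counts$meth[j, ], counts$total[j, ]), numeric(1))
  nps <- t(vapply(seq_len(m), function(j) {
    d <- dosage[j, ]
    c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
      sum(d == 2, na.rm = TRUE))
  }, numeric(3)))
  keep <- which(!is.na(mean_meth) & mean_meth >= mean_range[1] &
                mean_meth <= mean_range[2] &
                nps[, 1] >= min_per_state & nps[, 2] >= min_per_state &
                nps[, 3] >= min_per_state)
  attr(keep, "mean_methylation") <- mean_meth
  attr(keep, "n_per_state") <- nps
  keep
}

.cpg_dosage <- function(panel, n_sites) {
  rows <- which(panel$loci$type == "cpg")
  if (length(rows) != n_sites) {
    stop("panel CpG loci do not align with the count matrix", call. = FALSE)
  }
  panel$dosage[rows, , drop = FALSE]
}

# Fit one site; returns NULL-safe list used by scan() and permutations.
.fit_site <- function(meth, total, X, start = NULL, phi_start = NULL) {
  if (is.null(phi_start)) phi_start <- c(0.01, 0.15)
  fit <- tryCatch(betabinom_glm(meth, total, X, start = start,
                                phi_start = phi_start),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(list(ok = FALSE, fit = fit))
  }
  list(ok = TRUE, fit = fit)
}

#' Scan CpG sites for ancestry effects on methylation
#'
#' Per site, fits a beta-binomial regression of methylated counts on local
#' ancestry dosage (additive 0/1/2), global ancestry and optional
#' covariates; Wald p-values are calibrated against permutation nulls built
#' by shuffling the local dosage vectors across individuals (for the local
#' test) and shuffling global ancestry (for the global test), keeping all
#' other information fixed. Empirical q-values follow
#' [empirical_qvalues()]. Non-converged sites are flagged and excluded from
#' the q-value computation.
#'
#' @param counts A `meth_counts` object.
#' @param panel An `ancestry_panel`.
#' @param covariates Optional numeric matrix (individuals x covariates).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param sites Site indices to test (defaults to [filter_sites()] output).
#' @return data.frame of class `"ancestry_scan"`: per site `beta_local`,
#'   `beta_global`, `p_local`, `p_global`, `q_local`, `q_global`,
#'   `effect_local` (proportion scale, homozygous-anubis minus
#'   homozygous-yellow), `n0`, `n1`, `n2`, `converged`. Attribute
#'   `n_failed` counts non-converged sites.
#' @export
ancestry_scan <- function(counts, panel, covariates = NULL, n_perm = 10,
                          seed = 1L, sites = NULL) {
  if (is.null(sites)) sites <- filter_sites(counts, panel)
  dosage <- .cpg_dosage(panel, nrow(counts$meth))
  n <- ncol(counts$meth)
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  build_X <- function(dos, glob) {
    X <- cbind(`(Intercept)` = 1, local = dos, global = glob)
    if (!is.null(covm)) X <- cbind(X, covm)
    X
  }
  res <- data.frame(site = sites, beta_local = NA_real_,
                    beta_global = NA_real_, p_local = NA_real_,
                    p_global = NA_real_, q_local = NA_real_,
                    q_global = NA_real_, effect_local = NA_real_,
                    n0 = NA_integer_, n1 = NA_integer_, n2 = NA_integer_,
                    converged = FALSE)
  starts <- vector("list", length(sites))
  phis <- rep(0.05, length(sites))
  for (k in seq_along(sites)) {
    j <- sites[k]
    d <- dosage[j, ]
    X <- build_X(d, panel$global)
    f <- .fit_site(counts$meth[j, ], counts$total[j, ], X)
    res$n0[k] <- sum(d == 0, na.rm = TRUE)
    res$n1[k] <- sum(d == 1, na.rm = TRUE)
    res$n2[k] <- sum(d == 2, na.rm = TRUE)
    if (!f$ok) next
    fit <- f$fit
    starts[[k]] <- fit$coefficients
    phis[k] <- min(max(fit$phi, 1e-4), 0.9)
    res$beta_local[k] <- fit$coefficients["local"]
    res$beta_global[k] <- fit$coefficients["global"]
    res$p_local[k] <- fit$p.value["local"]
    res$p_global[k] <- fit$p.value["global"]
    res$effect_local[k] <- effect_to_proportion_scale(fit, "local")
    res$converged[k] <- TRUE
  }

  set.seed(.substream(seed, "scan_perm"))
  pool_local <- pool_global <- list()
  for (b in seq_len(n_perm)) {
    perm_l <- sample.int(n)
    perm_g <- sample.int(n)
    pl <- pg <- rep(NA_real_, length(sites))
    for (k in seq_along(sites)) {
      if (!res$converged[k]) next
      j <- sites[k]
      Xl <- build_X(dosage[j, perm_l], panel$global)
      fl <- .fit_site(counts$meth[j, ], counts$total[j, ], Xl,
                      start = starts[[k]], phi_start = phis[k])
      if (fl$ok) pl[k] <- fl$fit$p.value["local"]
      Xg <- build_X(dosage[j, ], panel$global[perm_g])
      fg <- .fit_site(counts$meth[j, ], counts$total[j, ], Xg,
                      start = starts[[k]], phi_start = phis[k])
      if (fg$ok) pg[k] <- fg$fit$p.value["global"]
    }
    pool_local[[b]] <- pl[!is.na(pl)]
    pool_global[[b]] <- pg[!is.na(pg)]
  }
  ok <- res$converged & !is.na(res$p_local)
  if (any(ok) && n_perm > 0) {
    ql <- empirical_qvalues(res$p_local[ok], unlist(pool_local), n_perm)
    res$q_local[ok] <- ql$qvalues
    qg <- empirical_qvalues(res$p_global[ok], unlist(pool_global), n_perm)
    res$q_global[ok] <- qg$qvalues
  }
  attr(res, "n_failed") <- sum(!res$converged)
  class(res) <- c("ancestry_scan", "data.frame")
  res
}

#' Test additivity of local-ancestry effects
#'
#' Likelihood-ratio test (1 df) comparing the additive dosage coding against
#' a three-level ancestry-state factor, per site. Small p-values indicate
#' departure from additivity (e.g. heterozygote advantage).
#'
#' @inheritParams ancestry_scan
#' @return data.frame with `site` and `additivity_p`.
#' @export
test_additivity <- function(counts, panel, covariates = NULL, sites = NULL) {
  if (is.null(sites)) sites <- filter_sites(counts, panel)
  dosage <- .cpg_dosage(panel, nrow(counts$meth))
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  out <- data.frame(site = sites, additivity_p = NA_real_)
  for (k in seq_along(sites)) {
    j <- sites[k]
    d <- dosage[j, ]
    X0 <- cbind(1, d, panel$global)
    X1 <- cbind(1, d == 1, d == 2, panel$global)
    if (!is.null(covm)) {
      X0 <- cbind(X0, covm); X1 <- cbind(X1, covm)
    }
    f0 <- tryCatch(betabinom_glm(counts$meth[j, ], counts$total[j, ], X0,
                                 se = FALSE), error = function(e) NULL)
    f1 <- tryCatch(betabinom_glm(counts$meth[j, ], counts$total[j, ], X1,
                                 se = FALSE), error = function(e) NULL)
    if (is.null(f0) || is.null(f1)) next
    # allow tiny optimizer slack in either direction
    ll1 <- max(f1$logLik, f0$logLik)
    out$additivity_p[k] <- pchisq(2 * (ll1 - f0$logLik), df = 1,
                                  lower.tail = FALSE)
  }
  out
}

#' Ancestry effect on the proportion (methylation-level) scale
#'
#' Difference in model-predicted mean methylation between the
#' homozygous-anubis (dosage 2) and homozygous-yellow (dosage 0) states,
#' with all other design columns held at their observed means. With
#' `per_allele = TRUE` the difference is halved.
#'
#' @param fit A converged `bbfit` whose design contains the dosage column.
#' @param dosage_col Name or index of the dosage column in the design.
#' @param per_allele Divide by 2 to express the effect per allele?
#' @return Proportion-scale effect in `[-1, 1]`.
#' @export
effect_to_proportion_scale <- function(fit, dosage_col = "local",
                                       per_allele = FALSE) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  xbar <- colMeans(fit$X)
  x2 <- x0 <- xbar
  x2[dosage_col] <- 2
  x0[dosage_col] <- 0
  eff <- plogis(sum(x2 * fit$coefficients)) -
    plogis(sum(x0 * fit$coefficients))
  if (per_allele) eff / 2 else eff
}
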