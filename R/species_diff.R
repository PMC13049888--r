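# Differential methylation between two unadmixed parental groups and its
# concordance with within-hybrid ancestry effects.

#' Site filters for the between-species comparison
#'
#' Retains sites covered (total > 0) in at least `min_ind` individuals of
#' each group, with mean coverage greater than `min_cov` reads (over all
#' individuals of both groups) and mean methylation within `mean_range`.
#'
#' @param counts_y,counts_a Lists with `meth`/`total` matrices (sites x
#'   individuals) for the yellow and anubis groups; individual sets must be
#'   disjoint (checked via column names when present).
#' @param min_ind Minimum covered individuals per group.
#' @param min_cov Mean-coverage threshold (strict).
#' @param mean_range Inclusive mean-methylation bounds.
#' @return Integer vector of retained site indices.
#' @export
filter_species_sites <- function(counts_y, counts_a, min_ind = 5,
                                 min_cov = 5, mean_range = c(0.1, 0.9)) {
  ny <- colnames(counts_y$total); na <- colnames(counts_a$total)
  if (!is.null(ny) && !is.null(na) && length(intersect(ny, na)) > 0) {
    stop("individual IDs overlap between the two species", call. = FALSE)
  }
  if (nrow(counts_y$meth) != nrow(counts_a$meth)) {
    stop("site universes differ between the two matrices", call. = FALSE)
  }
  m <- nrow(counts_y$meth)
  keep <- logical(m)
  for (j in seq_len(m)) {
    ty <- counts_y$total[j, ]; ta <- counts_a$total[j, ]
    if (sum(ty > 0) < min_ind || sum(ta > 0) < min_ind) next
    tot <- c(ty, ta)
    if (mean(tot) <= min_cov) next
    mm <- .site_mean_methylation(c(counts_y$meth[j, ], counts_a$meth[j, ]),
                                 tot)
    keep[j] <- !is.na(mm) && mm >= mean_range[1] && mm <= mean_range[2]
  }
  which(keep)
}

#' Test CpG sites for a species difference in methylation
#'
#' Beta-binomial regression of methylated counts on a species indicator
#' (anubis = 1) plus optional covariates (e.g. bisulfite conversion rate),
#' with an empirical null built by permuting the species-label vector across
#' samples.
#'
#' @inheritParams filter_species_sites
#' @param covariates Optional numeric matrix over the combined individuals
#'   (yellow columns first).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param sites Site indices (defaults to [filter_species_sites()]).
#' @return data.frame of class `"species_diff"`: per site `beta_species`
#'   (logit), `delta_species` (proportion scale, anubis minus yellow), `p`,
#'   `q`, `converged`, `skipped_reason`.
#' @export
test_species <- function(counts_y, counts_a, covariates = NULL, n_perm = 10,
                         seed = 1L, sites = NULL) {
  if (is.null(sites)) sites <- filter_species_sites(counts_y, counts_a)
  meth <- cbind(counts_y$meth, counts_a$meth)
  total <- cbind(counts_y$total, counts_a$total)
  species <- c(rep(0, ncol(counts_y$meth)), rep(1, ncol(counts_a$meth)))
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  build_X <- function(sp) {
    X <- cbind(`(Intercept)` = 1, species = sp)
    if (!is.null(covm)) X <- cbind(X, covm)
    X
  }
  res <- data.frame(site = sites, beta_species = NA_real_,
                    delta_species = NA_real_, p = NA_real_, q = NA_real_,
                    converged = FALSE, skipped_reason = "")
  starts <- vector("list", length(sites))
  phis <- rep(0.05, length(sites))
  for (k in seq_along(sites)) {
    j <- sites[k]
    cov_ok <- total[j, ] > 0
    if (sum(cov_ok & species == 0) < 2 || sum(cov_ok & species == 1) < 2) {
      res$skipped_reason[k] <- "fewer than 2 covered individuals per group"
      next
    }
    f <- .fit_site(meth[j, ], total[j, ], build_X(species))
    if (!f$ok) {
      res$skipped_reason[k] <- "non-convergence"
      next
    }
    fit <- f$fit
    starts[[k]] <- fit$coefficients
    phis[k] <- min(max(fit$phi, 1e-4), 0.9)
    res$beta_species[k] <- fit$coefficients["species"]
    res$p[k] <- fit$p.value["species"]
    # species indicator is 0/1: predicted-mean difference at covariate means
    xbar <- colMeans(fit$X)
    x1 <- x0 <- xbar
    x1["species"] <- 1; x0["species"] <- 0
    res$delta_species[k] <- plogis(sum(x1 * fit$coefficients)) -
      plogis(sum(x0 * fit$coefficients))
    res$converged[k] <- TRUE
  }
  set.seed(.substream(seed, "species_perm"))
  pool <- list()
  n <- length(species)
  for (b in seq_len(n_perm)) {
    sp <- species[sample.int(n)]
    pb <- rep(NA_real_, length(sites))
    for (k in seq_along(sites)) {
      if (!res$converged[k]) next
      f <- .fit_site(meth[sites[k], ], total[sites[k], ], build_X(sp),
                     start = starts[[k]], phi_start = phis[k])
      if (f$ok) pb[k] <- f$fit$p.value["species"]
    }
    pool[[b]] <- pb[!is.na(pb)]
  }
  ok <- res$converged & !is.na(res$p)
  if (any(ok) && n_perm > 0) {
    res$q[ok] <- empirical_qvalues(res$p[ok], unlist(pool), n_perm)$qvalues
  }
  class(res) <- c("species_diff", "data.frame")
  res
}

#' Concordance between species differences and within-hybrid ancestry effects
#'
#' Among species-significant sites, correlates the proportion-scale species
#' difference with the within-hybrid ancestry effect; tests the overlap of
#' the two significant sets with a two-sided Fisher's exact test
#' (minimum-likelihood method, as in [stats::fisher.test()]); and reports
#' the fraction of jointly significant sites whose effects agree in sign.
#'
#' @param species A `species_diff` result.
#' @param hybrid An `ancestry_scan` result over the same site universe
#'   (matched on the `site` column).
#' @param p_thresh Nominal p-value threshold defining species significance.
#' @param fdr_thresh q-value threshold defining ancestry significance.
#' @return List of class `"concordance_result"`: `pearson_r`,
#'   `spearman_rho`, `fisher_log2_or`, `fisher_ci` (log2), `fisher_p`,
#'   `frac_directionally_concordant`, `n_overlap`, `flagged` (TRUE when a
#'   margin is empty).
#' @export
concordance <- function(species, hybrid, p_thresh = 0.01,
                        fdr_thresh = 0.10) {
  m <- merge(as.data.frame(species), as.data.frame(hybrid), by = "site")
  m <- m[m$converged.x & m$converged.y, ]
  sig_sp <- !is.na(m$p) & m$p <= p_thresh
  sig_an <- !is.na(m$q_local) & m$q_local < fdr_thresh
  out <- list(pearson_r = NA_real_, spearman_rho = NA_real_,
              fisher_log2_or = NA_real_, fisher_ci = c(NA_real_, NA_real_),
              fisher_p = NA_real_,
              frac_directionally_concordant = NA_real_,
              n_overlap = sum(sig_sp & sig_an), flagged = FALSE)
  if (sum(sig_sp) >= 3) {
    out$pearson_r <- cor(m$delta_species[sig_sp], m$effect_local[sig_sp])
    out$spearman_rho <- cor(m$delta_species[sig_sp], m$effect_local[sig_sp],
                            method = "spearman")
  }
  tab <- table(factor(sig_sp, c(FALSE, TRUE)), factor(sig_an, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out$flagged <- TRUE
  } else {
    ft <- stats::fisher.test(tab)
    out$fisher_log2_or <- log2(ft$estimate[[1]])
    out$fisher_ci <- log2(ft$conf.int)
    out$fisher_p <- ft$p.value
  }
  joint <- sig_sp & sig_an
  if (any(joint)) {
    out$frac_directionally_concordant <-
      mean(sign(m$delta_species[joint]) == sign(m$effect_local[joint]))
  }
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Species-difference vs within-hybrid ancestry-effect concordance\n")
  cat(sprintf("  Pearson r = %.3f, Spearman rho = %.3f\n",
              x$pearson_r, x$spearman_rho))
  cat(sprintf("  Fisher log2(OR) = %.2f [%.2f, %.2f], p = %.3g%s\n",
              x$fisher_log2_or, x$fisher_ci[1], x$fisher_ci[2], x$fisher_p,
              if (x$flagged) " (degenerate margin)" else ""))
  cat(sprintf("  Directional concordance: %.1f%% of %d jointly significant sites\n",
              100 * x$frac_directionally_concordant, x$n_overlap))
  invisible(x)
}
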