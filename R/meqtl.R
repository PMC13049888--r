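# meQTL mapping from SNP-CpG pairs co-observed on reads: joint likelihood
# over the across-individual genotype effect and within-heterozygote
# allele-specific methylation, sharing one per-allele effect.

#' Build SNP-CpG pairs for meQTL mapping
#'
#' Applies the mapping filters: pair distance within `max_dist` bp, SNP
#' call rate at least `call_rate`, minor allele frequency at least
#' `maf_min`, CpG mean coverage at least `cov_min` and mean methylation
#' within `mean_range`. The `disrupted` flag is set when the SNP overlaps
#' either base of the CpG dinucleotide (distance 0 or 1).
#'
#' @param genotypes A `genotypes` object (alternate-allele dosage matrix).
#' @param counts A `meth_counts` object, including `allele_specific`.
#' @param pairs data.frame with columns `cpg_id`, `snp_id`, `distance` (bp).
#' @return List of class `"snp_cpg_pairs"`: element `pairs` (filtered pair
#'   table with `disrupted`), `data` (per-pair list: `geno`, `meth`,
#'   `total`, `as` allele-specific counts), plus attribute `filter_log`
#'   (input/output counts per rule).
#' @export
build_pairs <- function(genotypes, counts, pairs, max_dist = 100,
                        call_rate = 0.5, maf_min = 0.05, cov_min = 5,
                        mean_range = c(0.1, 0.9)) {
  if (ncol(genotypes$geno) != ncol(counts$meth)) {
    stop("genotype and count matrices have different individuals",
         call. = FALSE)
  }
  log <- list(input = nrow(pairs))
  keep <- pairs$distance <= max_dist
  log$within_distance <- sum(keep)
  cr <- rowMeans(!is.na(genotypes$geno[pairs$snp_id, , drop = FALSE]))
  f <- rowMeans(genotypes$geno[pairs$snp_id, , drop = FALSE],
                na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- keep & cr >= call_rate & maf >= maf_min
  log$snp_filters <- sum(keep)
  mean_cov <- rowMeans(counts$total[pairs$cpg_id, , drop = FALSE])
  mean_meth <- vapply(pairs$cpg_id, function(j)
    .site_mean_methylation(counts$meth[j, ], counts$total[j, ]), numeric(1))
  keep <- keep & mean_cov >= cov_min & !is.na(mean_meth) &
    mean_meth >= mean_range[1] & mean_meth <= mean_range[2]
  log$cpg_filters <- sum(keep)
  pt <- pairs[keep, , drop = FALSE]
  pt$disrupted <- pt$distance <= 1
  dat <- lapply(seq_len(nrow(pt)), function(k) {
    j <- pt$cpg_id[k]
    as_j <- counts$allele_specific[counts$allele_specific$cpg_id == j, ,
                                   drop = FALSE]
    list(geno = genotypes$geno[pt$snp_id[k], ],
         meth = counts$meth[j, ], total = counts$total[j, ], as = as_j)
  })
  structure(list(pairs = pt, data = dat),
            class = "snp_cpg_pairs", filter_log = log)
}

# Joint negative log-likelihood. par = (mu0, gamma, eta); phi = plogis(eta).
# Individual-level counts are read mixtures over the two haplotypes, so a
# dosage-d individual has mean ((2 - d) m_ref + d m_alt) / 2; heterozygote
# allele-specific counts contribute beta-binomial terms at m_ref / m_alt.
.meqtl_negll <- function(par, dat, null = FALSE) {
  mu0 <- par[1]
  gamma <- if (null) 0 else par[2]
  eta <- par[length(par)]
  m_ref <- plogis(mu0)
  m_alt <- plogis(mu0 + gamma)
  phi <- plogis(eta)
  mr <- min(max(m_ref, .MU_EPS), 1 - .MU_EPS)
  ma <- min(max(m_alt, .MU_EPS), 1 - .MU_EPS)
  mu_ind <- ((2 - dat$geno_c) * mr + dat$geno_c * ma) / 2
  mu_ind <- pmin(pmax(mu_ind, .MU_EPS), 1 - .MU_EPS)
  ll <- sum(.bb_logpmf(dat$meth_o, dat$total_o, mu_ind, phi))
  if (nrow(dat$as_c)) {
    ll <- ll + sum(.bb_logpmf(dat$as_c$meth_ref, dat$as_c$total_ref, mr, phi))
    ll <- ll + sum(.bb_logpmf(dat$as_c$meth_alt, dat$as_c$total_alt, ma, phi))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Assemble complete-case data for one pair: heterozygotes' allele-assignable
# reads are removed from the individual-level counts (no double counting).
.meqtl_data <- function(geno, meth, total, as) {
  ok <- !is.na(geno) & total > 0
  idx <- which(ok)
  meth_o <- meth[idx]
  total_o <- total[idx]
  if (nrow(as)) {
    pos <- match(as$individual, idx)
    hit <- !is.na(pos)
    meth_o[pos[hit]] <- meth_o[pos[hit]] - (as$meth_ref + as$meth_alt)[hit]
    total_o[pos[hit]] <- total_o[pos[hit]] -
      (as$total_ref + as$total_alt)[hit]
    as <- as[hit, , drop = FALSE]
  }
  list(geno_c = geno[idx], meth_o = pmax(meth_o, 0L),
       total_o = pmax(total_o, 0L), as_c = as)
}

#' Fit the joint meQTL model for one SNP-CpG pair
#'
#' Maximizes a composite likelihood with a single per-allele effect shared
#' by (a) the individual-level beta-binomial, whose mean for a dosage-d
#' individual is the read mixture `((2 - d) m_ref + d m_alt) / 2`, and (b)
#' within-heterozygote beta-binomial terms where reference-allele reads have
#' mean `m_ref` and alternate-allele reads `m_alt`, with
#' `m_ref = plogis(mu0)` and `m_alt = plogis(mu0 + beta)`. The p-value is a
#' 1-df likelihood-ratio test of `beta = 0`. Without heterozygote
#' allele-specific counts the fit degrades to the individual-level
#' component only (flagged).
#'
#' @param geno Alternate-allele dosage vector (0/1/2, NA allowed).
#' @param meth,total Count vectors at the CpG.
#' @param as Allele-specific counts for heterozygotes: data.frame with
#'   `individual`, `meth_ref`, `total_ref`, `meth_alt`, `total_alt`.
#' @return List: `beta` (allelic logit effect), `delta` (proportion-scale
#'   per-allele effect, alt minus ref), `mu0`, `phi`, `p`, `logLik_alt`,
#'   `logLik_null`, `converged`, `has_as` (allele-specific data present).
#' @export
fit_meqtl <- function(geno, meth, total,
                      as = data.frame(individual = integer(0),
                                      meth_ref = integer(0),
                                      total_ref = integer(0),
                                      meth_alt = integer(0),
                                      total_alt = integer(0)),
                      gamma_starts = c(0, 1, -1)) {
  dat <- .meqtl_data(geno, meth, total, as)
  if (length(dat$geno_c) < 3) stop("too few usable individuals",
                                   call. = FALSE)
  pooled <- sum(dat$meth_o) + sum(dat$as_c$meth_ref) + sum(dat$as_c$meth_alt)
  tot <- sum(dat$total_o) + sum(dat$as_c$total_ref) + sum(dat$as_c$total_alt)
  mu_start <- qlogis(min(max((pooled + 0.5) / (tot + 1), 0.01), 0.99))
  opt_null <- NULL
  for (ph in c(0.01, 0.15)) {
    o <- tryCatch(stats::optim(c(mu_start, qlogis(ph)), .meqtl_negll,
                               dat = dat, null = TRUE, method = "BFGS",
                               control = list(maxit = 300, reltol = 1e-9)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(opt_null) || o$value < opt_null$value)) {
      opt_null <- o
    }
  }
  if (is.null(opt_null)) stop("null optimization failed", call. = FALSE)
  opt_alt <- NULL
  for (g0 in gamma_starts) {
    o <- tryCatch(stats::optim(c(opt_null$par[1], g0, opt_null$par[2]),
                               .meqtl_negll, dat = dat, method = "BFGS",
                               control = list(maxit = 400, reltol = 1e-9)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(opt_alt) || o$value < opt_alt$value)) {
      opt_alt <- o
    }
  }
  if (is.null(opt_alt)) stop("alternative optimization failed", call. = FALSE)
  mu0 <- opt_alt$par[1]; gamma <- opt_alt$par[2]
  stat <- max(0, 2 * (opt_null$value - opt_alt$value))
  list(beta = gamma,
       delta = plogis(mu0 + gamma) - plogis(mu0),
       mu0 = mu0, phi = plogis(opt_alt$par[3]),
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       logLik_alt = -opt_alt$value, logLik_null = -opt_null$value,
       converged = opt_alt$convergence == 0 && opt_null$convergence == 0,
       has_as = nrow(dat$as_c) > 0)
}

#' Map meQTL over a set of SNP-CpG pairs
#'
#' Fits [fit_meqtl()] to every pair, builds the double permutation null
#' (genotypes shuffled across individuals, then each heterozygote's reads
#' re-assigned to alleles uniformly while preserving every individual's
#' methylated/total counts), and computes empirical q-values.
#'
#' @param built A `snp_cpg_pairs` object from [build_pairs()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return data.frame of class `"meqtl_result"`: per pair `cpg_id`,
#'   `snp_id`, `distance`, `disrupted`, `beta`, `delta`, `p`, `q`,
#'   `converged`, `has_as`.
#' @export
meqtl_scan <- function(built, n_perm = 10, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  pt <- built$pairs
  res <- cbind(pt[, c("cpg_id", "snp_id", "distance", "disrupted")],
               beta = NA_real_, delta = NA_real_, p = NA_real_,
               q = NA_real_, converged = FALSE, has_as = FALSE)
  for (k in seq_len(nrow(pt))) {
    d <- built$data[[k]]
    f <- tryCatch(fit_meqtl(d$geno, d$meth, d$total, d$as),
                  error = function(e) NULL)
    if (is.null(f)) next
    res$beta[k] <- f$beta; res$delta[k] <- f$delta; res$p[k] <- f$p
    res$converged[k] <- f$converged; res$has_as[k] <- f$has_as
  }
  set.seed(.substream(seed, "meqtl_perm"))
  pool <- list()
  n_ind <- length(built$data[[1]]$geno)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_ind)
    pb <- rep(NA_real_, nrow(pt))
    for (k in seq_len(nrow(pt))) {
      if (!res$converged[k]) next
      d <- built$data[[k]]
      pg <- permute_pair(d, perm)
      f <- tryCatch(fit_meqtl(pg$geno, pg$meth, pg$total, pg$as,
                              gamma_starts = 0),
                    error = function(e) NULL)
      if (!is.null(f) && f$converged) pb[k] <- f$p
    }
    pool[[b]] <- pb[!is.na(pb)]
  }
  ok <- res$converged & !is.na(res$p)
  if (any(ok)) {
    res$q[ok] <- empirical_qvalues(res$p[ok], unlist(pool), n_perm)$qvalues
  }
  class(res) <- c("meqtl_result", "data.frame")
  res
}

#' Permute one pair's data for the meQTL null
#'
#' Applies a genotype permutation across individuals; individuals who are
#' heterozygous after permutation keep their own allele-assignable reads but
#' with allele labels re-drawn uniformly (reference total binomial(T, 1/2),
#' methylated reads hypergeometric given the per-read methylation states);
#' other individuals' assignable reads rejoin the individual-level counts.
#' Every individual's (meth, total) marginals are preserved exactly.
#'
#' @param d Per-pair data list (`geno`, `meth`, `total`, `as`).
#' @param perm Permutation of the individual indices.
#' @return A list with the same shape as `d`.
#' @export
permute_pair <- function(d, perm) {
  geno_p <- d$geno[perm]
  het_now <- which(!is.na(geno_p) & geno_p == 1L)
  as_old <- d$as
  keep <- as_old[as_old$individual %in% het_now, , drop = FALSE]
  if (nrow(keep)) {
    T_as <- keep$total_ref + keep$total_alt
    M_as <- keep$meth_ref + keep$meth_alt
    tr <- rbinom(nrow(keep), T_as, 0.5)
    mr <- rhyper(nrow(keep), M_as, T_as - M_as, tr)
    keep$total_ref <- tr
    keep$total_alt <- T_as - tr
    keep$meth_ref <- mr
    keep$meth_alt <- M_as - mr
  }
  list(geno = geno_p, meth = d$meth, total = d$total, as = keep)
}

#' Disrupted-CpG composition regression
#'
#' For CpG-disrupting meQTL, regresses the observed proportion-scale
#' ancestry effect on the composition predictor (parental allele-frequency
#' difference times the disrupting-allele effect) and reports the slope and
#' correlation.
#'
#' @param observed_effect Observed ancestry effects.
#' @param delta Disrupting-allele effects (proportion scale).
#' @param dfreq Parental frequency differences (anubis minus yellow).
#' @return List: `slope`, `intercept`, `r`, `r_squared`, `n`, `flagged`
#'   (TRUE with reason when under 3 points or the predictor is constant).
#' @export
disruption_regression <- function(observed_effect, delta, dfreq) {
  pred <- delta * dfreq
  ok <- is.finite(observed_effect) & is.finite(pred)
  if (sum(ok) < 3) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, n = sum(ok), flagged = TRUE,
                reason = "fewer than 3 points"))
  }
  if (length(unique(pred[ok])) == 1) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, n = sum(ok), flagged = TRUE,
                reason = "constant predictor"))
  }
  fit <- stats::lm(observed_effect[ok] ~ pred[ok])
  r <- cor(pred[ok], observed_effect[ok])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, r_squared = r^2, n = sum(ok), flagged = FALSE, reason = "")
}

#' Detection probability versus SNP-CpG distance
#'
#' Logistic regression of meQTL detection (q below `q_thresh`) on base-pair
#' distance, excluding CpG-disrupting pairs.
#'
#' @param results A `meqtl_result` data.frame.
#' @param q_thresh Detection threshold.
#' @param min_pairs Minimum number of non-disrupted pairs required.
#' @return List: `slope` (per bp), `p`, `n`, `separation` flag.
#' @export
distance_effect <- function(results, q_thresh = 0.10, min_pairs = 50) {
  r <- results[!results$disrupted & results$converged & !is.na(results$q), ]
  if (nrow(r) == 0) stop("no usable pairs", call. = FALSE)
  if (nrow(r) < min_pairs) {
    stop(sprintf("need at least %d non-disrupted pairs", min_pairs),
         call. = FALSE)
  }
  detected <- as.integer(r$q < q_thresh)
  if (length(unique(detected)) == 1) {
    return(list(slope = NA_real_, p = NA_real_, n = nrow(r),
                separation = TRUE))
  }
  fit <- suppressWarnings(stats::glm(detected ~ r$distance,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], p = sm[2, 4], n = nrow(r), separation = FALSE)
}
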