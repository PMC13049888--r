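# How admixture shifts meQTL allele frequencies and inflates methylation
# variance: ancestry-homozygous subset vs the full sample.

#' Minor-allele frequency shift due to admixture
#'
#' Per SNP, compares the allele frequency in the locally homozygous-yellow
#' subset (dosage 0 at the SNP's locus) with the full sample. The minor
#' allele is defined in the subset and the same allele is tracked in the
#' full-sample estimate, so the shift reads as admixture-introduced
#' frequency change. Reports a paired t-test over SNPs, the stratum of SNPs
#' rare in the subset (frequency <= `low_freq`), and the count of variants
#' invariant in the subset but polymorphic overall.
#'
#' @param genotypes A `genotypes` object (or alternate-allele dosage matrix).
#' @param dosage_at_snps Local-ancestry dosage matrix aligned to the SNP
#'   rows (anubis allele count 0/1/2).
#' @param snp_set Row indices of the SNPs to assess (default: all).
#' @param min_subset Minimum subset individuals per SNP.
#' @param low_freq Threshold for the rare-in-subset stratum.
#' @return List of class `"maf_shift"`: `per_snp` data.frame (`snp`,
#'   `maf_subset`, `maf_full`, `shift`, `n_subset`), `mean_shift`,
#'   `paired_t_p`, `low_freq_stratum` (mean shift and p among subset-rare
#'   SNPs), `n_introduced` (invariant in subset, polymorphic overall),
#'   `skipped` (SNPs without enough subset individuals).
#' @export
maf_shift <- function(genotypes, dosage_at_snps, snp_set = NULL,
                      min_subset = 2, low_freq = 0.10) {
  geno <- if (inherits(genotypes, "genotypes")) genotypes$geno else genotypes
  if (is.null(snp_set)) snp_set <- seq_len(nrow(geno))
  per <- data.frame(snp = snp_set, maf_subset = NA_real_,
                    maf_full = NA_real_, shift = NA_real_,
                    n_subset = NA_integer_)
  for (i in seq_along(snp_set)) {
    s <- snp_set[i]
    g <- geno[s, ]
    sub <- which(dosage_at_snps[s, ] == 0 & !is.na(g))
    per$n_subset[i] <- length(sub)
    if (length(sub) < min_subset) next
    f_sub <- mean(g[sub]) / 2
    # orient by the subset's minor allele and hold that allele fixed
    flip <- f_sub > 0.5
    f_sub_o <- if (flip) 1 - f_sub else f_sub
    f_full <- mean(g[!is.na(g)]) / 2
    f_full_o <- if (flip) 1 - f_full else f_full
    per$maf_subset[i] <- f_sub_o
    per$maf_full[i] <- f_full_o
    per$shift[i] <- f_full_o - f_sub_o
  }
  ok <- !is.na(per$shift)
  tt <- if (sum(ok) >= 2 && stats::sd(per$shift[ok]) > 0) {
    stats::t.test(per$maf_full[ok], per$maf_subset[ok], paired = TRUE)
  } else NULL
  rare <- ok & per$maf_subset <= low_freq
  tt_rare <- if (sum(rare) >= 2 && stats::sd(per$shift[rare]) > 0) {
    stats::t.test(per$maf_full[rare], per$maf_subset[rare], paired = TRUE)
  } else NULL
  out <- list(
    per_snp = per,
    mean_shift = mean(per$shift[ok]),
    sd_shift = stats::sd(per$shift[ok]),
    paired_t_p = if (is.null(tt)) NA_real_ else tt$p.value,
    low_freq_stratum = list(
      n = sum(rare), mean_shift = mean(per$shift[rare]),
      paired_t_p = if (is.null(tt_rare)) NA_real_ else tt_rare$p.value),
    n_introduced = sum(ok & per$maf_subset == 0 & per$maf_full > 0),
    skipped = sum(!ok))
  class(out) <- "maf_shift"
  out
}

#' Methylation-variance gain from admixture
#'
#' Per CpG, compares the standard deviation of per-individual methylation
#' ratios (methylated/total reads) between the locally homozygous-yellow
#' subset and the full sample. Gains are summarized per site class with
#' paired t-tests.
#'
#' @param counts A `meth_counts` object.
#' @param dosage_at_cpgs Local-ancestry dosage matrix aligned to CpG rows.
#' @param site_class Optional character vector (one label per CpG row)
#'   defining strata, e.g. "meqtl_ancestry", "meqtl_only", "other".
#' @param min_subset Minimum covered subset individuals per site.
#' @return List of class `"sd_gain"`: `per_site` data.frame (`site`,
#'   `class`, `sd_subset`, `sd_full`, `pct_gain`), `by_class` data.frame
#'   (`class`, `n`, `mean_pct_gain`, `paired_t_p`).
#' @export
sd_gain <- function(counts, dosage_at_cpgs, site_class = NULL,
                    min_subset = 10) {
  m <- nrow(counts$meth)
  if (is.null(site_class)) site_class <- rep("all", m)
  per <- data.frame(site = seq_len(m), class = site_class,
                    sd_subset = NA_real_, sd_full = NA_real_,
                    pct_gain = NA_real_)
  for (j in seq_len(m)) {
    tot <- counts$total[j, ]
    cov_ok <- tot > 0
    sub <- cov_ok & dosage_at_cpgs[j, ] == 0
    if (sum(sub) < min_subset) next
    ratio <- counts$meth[j, ] / tot
    sds <- stats::sd(ratio[sub])
    sdf <- stats::sd(ratio[cov_ok])
    per$sd_subset[j] <- sds
    per$sd_full[j] <- sdf
    per$pct_gain[j] <- if (sds > 0) 100 * (sdf / sds - 1) else NA_real_
  }
  classes <- unique(site_class)
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    rows <- per$class == cl & !is.na(per$pct_gain)
    p <- if (sum(rows) >= 2 &&
             stats::sd(per$sd_full[rows] - per$sd_subset[rows]) > 0) {
      stats::t.test(per$sd_full[rows], per$sd_subset[rows],
                    paired = TRUE)$p.value
    } else NA_real_
    data.frame(class = cl, n = sum(rows),
               mean_pct_gain = mean(per$pct_gain[rows]), paired_t_p = p)
  }))
  out <- list(per_site = per, by_class = by_class)
  class(out) <- "sd_gain"
  out
}

#' Variance gain versus local introgressed-ancestry frequency
#'
#' Ordinary least squares of per-site variance gain on the local
#' anubis-ancestry frequency at that site.
#'
#' @param gains Per-site percent gains (e.g. `per_site$pct_gain` from
#'   [sd_gain()]).
#' @param introgression Per-site anubis-ancestry frequency (mean dosage / 2).
#' @param min_sites Minimum sites required.
#' @return List: `slope`, `p`, `n`, `degenerate` (constant predictor flag).
#' @export
gain_vs_introgression <- function(gains, introgression, min_sites = 20) {
  ok <- is.finite(gains) & is.finite(introgression)
  if (sum(ok) < min_sites) {
    stop(sprintf("need at least %d sites", min_sites), call. = FALSE)
  }
  if (length(unique(introgression[ok])) == 1) {
    return(list(slope = NA_real_, p = NA_real_, n = sum(ok),
                degenerate = TRUE))
  }
  fit <- stats::lm(gains[ok] ~ introgression[ok])
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], p = sm[2, 4], n = sum(ok), degenerate = FALSE)
}
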