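# Shared fixtures, built once per test run.

# Simple count matrices with a fixed per-site methylation level.
make_counts <- function(n_sites, n_ind, m, coverage = 20, seed = 1,
                        prefix = "ind") {
  set.seed(seed)
  total <- matrix(rnbinom(n_sites * n_ind, mu = coverage, size = 8),
                  n_sites, n_ind)
  m <- rep_len(m, n_sites)
  meth <- matrix(rbinom(n_sites * n_ind, total, rep(m, n_ind)),
                 n_sites, n_ind)
  colnames(meth) <- colnames(total) <- paste0(prefix, seq_len(n_ind))
  list(meth = meth, total = total)
}

# Worked biallelic-meQTL scenario: reference allele never methylated, the
# alternate methylated half the time, segregating at 25% in yellow and fixed
# in anubis. Returns a full cohort built from hand-set frequencies/truth.
make_worked_example_cohort <- function(n = 300, coverage = 20, alpha = 0.5,
                                       m_ref = 0, m_alt = 0.5,
                                       p_yellow = 0.25, p_anubis = 1.0,
                                       bb_dispersion = 0, seed = 7) {
  cfg <- sim_config(n_individuals = n, n_snps = 1, n_cpgs = 1,
                    frac_meqtl = 1, frac_disrupted = 0,
                    mean_coverage = coverage, bb_dispersion = bb_dispersion,
                    admix_alpha = alpha, mean_tract_bp = 3e5, seed = seed)
  layout <- list(
    loci = data.frame(chrom = 1L, pos = c(10000L, 10010L),
                      type = c("cpg", "snp"), id = c(1L, 1L)),
    pairs = data.frame(cpg_id = 1L, snp_id = 1L, distance = 10L,
                       disrupted = FALSE))
  freqs <- data.frame(snp_id = 1L, p_yellow = p_yellow, p_anubis = p_anubis,
                      is_aim = abs(p_anubis - p_yellow) >= 0.2)
  panel <- simulate_ancestry(cfg, layout$loci)
  # with a two-locus layout the mean-dosage global estimate is collinear
  # with the local dosage; emulate a genome-wide estimate instead
  set.seed(seed + 1L)
  panel$global <- pmin(pmax(rnorm(n, alpha, 0.05), 0), 1)
  genotypes <- simulate_genotypes(panel, freqs, cfg$seed)
  truth <- data.frame(cpg_id = 1L, baseline_logit = qlogis(0.2),
                      snp_id = 1L, m_ref = m_ref, m_alt = m_alt,
                      true_delta = m_alt - m_ref, is_disrupted = FALSE,
                      true_ancestry_effect = (m_alt - m_ref) *
                        (p_anubis - p_yellow))
  counts <- simulate_methylation(genotypes, truth, panel, layout, cfg)
  list(config = cfg, freqs = freqs, layout = layout, panel = panel,
       genotypes = genotypes, truth = truth, counts = counts)
}

# A moderate admixed cohort with meQTL, reused across test files.
shared_cohort <- local({
  cfg <- sim_config(n_individuals = 300, n_snps = 120, n_cpgs = 100,
                    frac_meqtl = 0.5, frac_disrupted = 0.1,
                    mean_coverage = 20, bb_dispersion = 0.02,
                    admix_alpha = 0.4, mean_tract_bp = 3e5,
                    effect_sd_logit = 1.5, seed = 42)
  simulate_cohort(cfg)
})
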