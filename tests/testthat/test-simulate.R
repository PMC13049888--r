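# Synthetic-data generator: parental divergence, ancestry mosaics,
# genotypes, methylation reads, reporter counts.

test_that("parental frequencies follow the requested divergence", {
  # no-drift limit
  f0 <- simulate_parental_frequencies(10000, 1e-6, 3)
  expect_lt(mean(abs(f0$p_anubis - f0$p_yellow)), 0.01)
  # Hudson's Fst estimator recovers the drift parameter
  f <- simulate_parental_frequencies(50000, 0.28, 3)
  expect_lt(abs(fst_hudson(f$p_yellow, f$p_anubis) - 0.28), 0.05)
  expect_true(all(f$is_aim == (abs(f$p_anubis - f$p_yellow) >= 0.2)))
  # the AIM fraction grows with divergence
  aim_frac <- vapply(c(0.05, 0.1, 0.2, 0.3), function(F)
    mean(simulate_parental_frequencies(20000, F, 3)$is_aim), numeric(1))
  expect_true(all(diff(aim_frac) > 0))
  expect_error(simulate_parental_frequencies(10, 0, 1), "divergence_F")
  expect_error(simulate_parental_frequencies(10, NaN, 1), "divergence_F")
})

test_that("ancestry mosaics have the right admixture level and tract length", {
  cfg0 <- sim_config(n_individuals = 20, n_cpgs = 30, n_snps = 30,
                     admix_alpha = 0, seed = 2)
  lay0 <- simulate_loci(cfg0)
  pan0 <- simulate_ancestry(cfg0, lay0$loci)
  expect_true(all(pan0$dosage == 0))
  expect_true(all(pan0$global == 0))

  cfg <- sim_config(n_individuals = 200, n_cpgs = 50, n_snps = 50,
                    admix_alpha = 0.37, chrom_length = 2e7,
                    mean_tract_bp = 2e5, seed = 2)
  lay <- simulate_loci(cfg)
  pan <- simulate_ancestry(cfg, lay$loci)
  expect_lt(abs(mean(pan$global) - 0.37), 0.03)
  tr <- pan$tracts
  interior <- tr$start > 0 & tr$end < cfg$chrom_length
  expect_gte(sum(interior), 1000)
  obs <- mean((tr$end - tr$start)[interior])
  expect_lt(abs(obs - cfg$mean_tract_bp) / cfg$mean_tract_bp, 0.15)
  # per-individual global ancestry equals mean dosage / 2
  expect_equal(pan$global, colMeans(pan$dosage) / 2)
})

test_that("seed fixes generator output bit-for-bit", {
  cfg <- sim_config(n_individuals = 30, n_cpgs = 20, n_snps = 25, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$meth, b$counts$meth)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$panel$tracts, b$panel$tracts)
  expect_identical(a$counts$allele_specific, b$counts$allele_specific)
})

test_that("genotypes track local ancestry and parental frequencies", {
  cfg <- sim_config(n_individuals = 500, n_cpgs = 10, n_snps = 20,
                    admix_alpha = 0.5, mean_tract_bp = 3e5, seed = 12)
  lay <- simulate_loci(cfg)
  pan <- simulate_ancestry(cfg, lay$loci)
  freqs <- simulate_parental_frequencies(20, 0.28, 12)
  g <- simulate_genotypes(pan, freqs, 12)

  # a locus absent from both parents is monomorphic
  freqs0 <- freqs; freqs0$p_yellow[1] <- 0; freqs0$p_anubis[1] <- 0
  g0 <- simulate_genotypes(pan, freqs0, 12)
  expect_true(all(g0$geno[1, ] == 0))

  snp_rows <- g$snp_rows
  s <- which.max(pmin(freqs$p_yellow, 1 - freqs$p_yellow))
  hom_y <- pan$dosage[snp_rows[s], ] == 0
  n_al <- 2 * sum(hom_y)
  k <- sum(g$geno[s, hom_y])
  ci <- binom.test(k, n_al)$conf.int
  expect_gte(freqs$p_yellow[s], ci[1])
  expect_lte(freqs$p_yellow[s], ci[2])

  # HWE within the ancestry-homozygous subset
  p_hat <- k / n_al
  ex <- sum(hom_y) * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  obs <- table(factor(g$geno[s, hom_y], 0:2))
  keep <- ex > 0
  chi <- sum((obs[keep] - ex[keep])^2 / ex[keep])
  expect_gt(pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.001)

  expect_error(simulate_genotypes(pan, freqs[1:5, ], 1), "misaligned")
})

test_that("methylation reads follow the per-allele model", {
  # both alleles unmethylated: no methylated read anywhere
  coh0 <- make_worked_example_cohort(n = 50, m_ref = 0, m_alt = 0,
                                     seed = 3)
  expect_true(all(coh0$counts$meth == 0))

  # worked example: alternate allele at 25% in an unadmixed yellow
  # population, methylated half the time; mean methylation 12.5%
  coh <- make_worked_example_cohort(n = 500, coverage = 30, alpha = 0,
                                    seed = 4)
  ratio <- coh$counts$meth[1, ] / pmax(coh$counts$total[1, ], 1)
  expect_lt(abs(mean(ratio[coh$counts$total[1, ] > 0]) - 0.125), 0.02)

  # zero dispersion: per-site counts are binomial (overdispersion test)
  cohb <- make_worked_example_cohort(n = 800, coverage = 30, alpha = 0,
                                     m_ref = 0.4, m_alt = 0.4,
                                     bb_dispersion = 0, seed = 5)
  meth <- cohb$counts$meth[1, ]; tot <- cohb$counts$total[1, ]
  p_hat <- sum(meth) / sum(tot)
  # dispersion statistic: sum of squared Pearson residuals ~ chi2(n - 1)
  keep <- tot > 0
  X2 <- sum((meth[keep] - tot[keep] * p_hat)^2 /
              (tot[keep] * p_hat * (1 - p_hat)))
  expect_gt(pchisq(X2, df = sum(keep) - 1, lower.tail = FALSE), 0.001)

  # heterozygote allele-specific counts nest within individual totals
  as <- shared_cohort$counts$allele_specific
  expect_gt(nrow(as), 0)
  tot_i <- shared_cohort$counts$total[cbind(as$cpg_id, as$individual)]
  expect_true(all(as$total_ref + as$total_alt <= tot_i))
  g_at <- mapply(function(cpg, ind)
    shared_cohort$genotypes$geno[shared_cohort$truth$snp_id[cpg], ind],
    as$cpg_id, as$individual)
  expect_true(all(g_at == 1))
})

test_that("expected-methylation variance matches the HWE closed form", {
  # 2p(1-p)((m1-m0)/2)^2 at high coverage, zero dispersion
  coh <- make_worked_example_cohort(n = 2000, coverage = 400, alpha = 0,
                                    m_ref = 0.1, m_alt = 0.9,
                                    p_yellow = 0.5, p_anubis = 0.5,
                                    seed = 6)
  p <- mean(coh$genotypes$geno[1, ]) / 2
  cf <- 2 * p * (1 - p) * ((0.9 - 0.1) / 2)^2
  emp <- var(coh$counts$meth[1, ] / coh$counts$total[1, ])
  expect_lt(abs(emp - cf) / cf, 0.05)
})

test_that("reporter generator honours truth labels and errors", {
  expect_error(simulate_reporter(100, frac_active = 0.02,
                                 frac_meth_dependent = 0.05),
               "cannot exceed")
  rep0 <- simulate_reporter(200, frac_active = 0, frac_meth_dependent = 0,
                            seed = 8)
  expect_true(all(rep0$windows$mult_meth == 1 & rep0$windows$mult_unmeth == 1))
  rep1 <- simulate_reporter(500, frac_active = 0.1,
                            frac_meth_dependent = 0.06, seed = 8)
  expect_equal(sum(rep1$windows$is_active), 50)
  expect_equal(sum(rep1$windows$is_meth_dependent), 30)
  # determinism
  rep2 <- simulate_reporter(500, frac_active = 0.1,
                            frac_meth_dependent = 0.06, seed = 8)
  expect_identical(rep1$counts, rep2$counts)
})

test_that("writers round-trip counts and emit valid VCF genotypes", {
  tmp <- tempfile(fileext = ".tsv")
  write_counts_tsv(shared_cohort$counts, tmp)
  back <- read_counts_tsv(tmp)
  expect_equal(unname(back$meth), unname(shared_cohort$counts$meth))
  expect_equal(unname(back$total), unname(shared_cohort$counts$total))

  vcf <- tempfile(fileext = ".vcf")
  snp_loci <- shared_cohort$panel$loci[
    shared_cohort$panel$loci$type == "snp", ]
  write_genotypes_vcf(shared_cohort$genotypes, snp_loci, vcf)
  lines <- readLines(vcf)
  expect_true(startsWith(lines[1], "##fileformat=VCF"))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(snp_loci))
  gt1 <- strsplit(body[1], "\t")[[1]][-(1:9)]
  dosage <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt1]
  expect_equal(unname(dosage), unname(shared_cohort$genotypes$geno[1, ]))
})
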