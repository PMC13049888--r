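# meQTL mapping: pair filters, joint likelihood, permutation contract,
# disruption regression, distance effect.

test_that("pair building enforces distance, MAF and CpG filters", {
  coh <- shared_cohort
  pairs <- coh$layout$pairs
  built <- build_pairs(coh$genotypes, coh$counts, pairs)
  lg <- attr(built, "filter_log")
  expect_equal(lg$input, nrow(pairs))
  # every retained pair respects the filters
  f <- rowMeans(coh$genotypes$geno[built$pairs$snp_id, , drop = FALSE]) / 2
  expect_true(all(pmin(f, 1 - f) >= 0.05))
  expect_true(all(built$pairs$distance <= 100))
  expect_identical(built$pairs$disrupted, built$pairs$distance <= 1)

  # a pair beyond 100 bp is excluded
  far <- pairs[1, ]; far$distance <- 101
  b2 <- build_pairs(coh$genotypes, coh$counts, far)
  expect_equal(nrow(b2$pairs), 0)

  # a rare SNP (MAF < 0.05) is excluded even within distance
  g3 <- coh$genotypes
  g3$geno[pairs$snp_id[1], ] <- c(1L, rep(0L, ncol(g3$geno) - 1))
  b3 <- build_pairs(g3, coh$counts, pairs[1, ])
  expect_equal(nrow(b3$pairs), 0)
})

test_that("joint fit recovers the worked-example allelic effect", {
  coh <- make_worked_example_cohort(n = 300, coverage = 20, alpha = 0.5,
                                    seed = 17)
  built <- build_pairs(coh$genotypes, coh$counts, coh$layout$pairs)
  expect_equal(nrow(built$pairs), 1)
  d <- built$data[[1]]
  fit <- fit_meqtl(d$geno, d$meth, d$total, d$as)
  expect_true(fit$converged)
  expect_lt(abs(fit$delta - 0.5), 0.05)
  expect_lt(fit$p, 1e-10)
  expect_true(fit$has_as)
})

test_that("allele-specific counts alone carry the signal", {
  # 50 heterozygotes, 20 reads per allele, m_ref = 0.2 vs m_alt = 0.8;
  # no individual-level contrast (all individuals are heterozygous)
  set.seed(71)
  n_het <- 50
  as <- data.frame(individual = seq_len(n_het),
                   meth_ref = rbinom(n_het, 20, 0.2), total_ref = 20L,
                   meth_alt = rbinom(n_het, 20, 0.8), total_alt = 20L)
  geno <- rep(1L, n_het)
  total <- as$total_ref + as$total_alt
  meth <- as$meth_ref + as$meth_alt
  fit <- fit_meqtl(geno, meth, total, as)
  expect_lt(fit$p, 1e-6)
  expect_gt(fit$delta, 0.4)

  # binomial comparison oracle on the pooled allele counts
  oracle_p <- prop.test(c(sum(as$meth_alt), sum(as$meth_ref)),
                        c(sum(as$total_alt), sum(as$total_ref)))$p.value
  expect_lt(oracle_p, 1e-6)
})

test_that("null pairs give small effects and uniform-ish p-values", {
  set.seed(72)
  ps <- replicate(30, {
    n <- 150
    geno <- rbinom(n, 2, 0.4)
    total <- rnbinom(n, mu = 20, size = 8)
    meth <- rbinom(n, total, 0.4)
    fit <- fit_meqtl(geno, meth, total)
    c(fit$delta, fit$p)
  })
  expect_lt(abs(mean(ps[1, ])), 0.03)
  expect_gt(mean(ps[2, ] > 0.1), 0.6)
})

test_that("permutation preserves per-individual count marginals exactly", {
  coh <- shared_cohort
  built <- build_pairs(coh$genotypes, coh$counts, coh$layout$pairs)
  d <- built$data[[which(vapply(built$data, function(x) nrow(x$as) > 5,
                                logical(1)))[1]]]
  set.seed(73)
  pg <- permute_pair(d, sample.int(length(d$geno)))
  expect_identical(pg$meth, d$meth)
  expect_identical(pg$total, d$total)
  expect_identical(sort(pg$geno), sort(d$geno))
  # re-drawn allele labels preserve each heterozygote's assignable totals
  common <- intersect(pg$as$individual, d$as$individual)
  a_new <- pg$as[match(common, pg$as$individual), ]
  a_old <- d$as[match(common, d$as$individual), ]
  expect_equal(a_new$total_ref + a_new$total_alt,
               a_old$total_ref + a_old$total_alt)
  expect_equal(a_new$meth_ref + a_new$meth_alt,
               a_old$meth_ref + a_old$meth_alt)
})

test_that("disrupted meQTL are detected with negative disrupting effects", {
  coh <- shared_cohort
  built <- build_pairs(coh$genotypes, coh$counts, coh$layout$pairs)
  dis <- which(built$pairs$disrupted)
  # only consider disrupted CpGs with appreciable baseline methylation
  base <- coh$truth$m_ref[built$pairs$cpg_id[dis]]
  dis <- dis[base >= 0.1]
  expect_gt(length(dis), 0)
  hits <- vapply(dis, function(k) {
    d <- built$data[[k]]
    f <- fit_meqtl(d$geno, d$meth, d$total, d$as)
    f$p < 0.01 && f$delta < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("disruption regression and distance effect behave as expected", {
  set.seed(74)
  dfreq <- runif(200, -1, 1)
  delta <- runif(200, -0.9, -0.1)
  obs <- delta * dfreq
  perfect <- disruption_regression(obs, delta, dfreq)
  expect_equal(perfect$slope, 1, tolerance = 1e-8)
  expect_equal(perfect$r, 1, tolerance = 1e-8)
  noisy <- disruption_regression(obs + rnorm(200, 0, 0.05), delta, dfreq)
  expect_gt(noisy$r, 0.7)
  expect_lte(noisy$r, 1)
  degen <- disruption_regression(obs, delta, rep(0, 200))
  expect_true(degen$flagged)
  expect_match(degen$reason, "constant")
  expect_true(disruption_regression(obs[1:2], delta[1:2], dfreq[1:2])$flagged)

  # distance effect: simulated decay of detection with distance
  set.seed(75)
  n <- 400
  dist <- sample(2:100, n, replace = TRUE)
  res <- data.frame(cpg_id = 1:n, snp_id = 1:n, distance = dist,
                    disrupted = FALSE, beta = 0, delta = 0, p = 0.5,
                    q = ifelse(runif(n) < plogis(2 - 0.05 * dist), 0.01, 0.5),
                    converged = TRUE, has_as = TRUE)
  de <- distance_effect(res)
  expect_lt(de$slope, 0)
  expect_lt(de$p, 0.05)

  # flat truth: confidence interval covers zero
  res$q <- ifelse(runif(n) < 0.5, 0.01, 0.5)
  de2 <- distance_effect(res)
  expect_gt(de2$p, 0.01)

  expect_error(distance_effect(res[0, ]), "no usable pairs")
  all_same <- res; all_same$q <- 0.01
  expect_true(distance_effect(all_same)$separation)
})
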