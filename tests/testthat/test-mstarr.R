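# Reporter-assay analysis: filters, normalization, activity and
# methylation-dependence calls.

test_that("window filters apply the three retention rules in order", {
  rep <- simulate_reporter(50, frac_active = 0.2, frac_meth_dependent = 0.1,
                           seed = 31)
  rm <- reporter_matrix(rep$counts)
  dna_m <- which(rm$meta$assay == "DNA" & rm$meta$condition == "methylated")
  rna <- which(rm$meta$assay == "RNA")
  # window 1: DNA median exactly 4 in one condition -> dropped (strict rule)
  rm$mat[1, dna_m] <- 4L
  # window 2: all RNA zero -> dropped by rule iii
  rm$mat[2, rna] <- 0L
  # window 3: DNA present in under half the methylated replicates
  rm$mat[3, dna_m] <- c(0L, 0L, 0L, 0L, 9L, 9L)
  keep <- filter_windows(rm$mat, rm$meta)
  expect_false(1 %in% keep)
  expect_false(2 %in% keep)
  expect_false(3 %in% keep)
  # RNA non-zero in exactly half the replicates of one treatment passes iii
  rna_m <- which(rm$meta$assay == "RNA" & rm$meta$condition == "methylated")
  rna_u <- which(rm$meta$assay == "RNA" & rm$meta$condition == "unmethylated")
  rm$mat[4, rna_m] <- c(0L, 0L, 0L, 5L, 5L, 5L)
  rm$mat[4, rna_u] <- 0L
  expect_true(4 %in% filter_windows(rm$mat, rm$meta))

  bad_meta <- rm$meta[rm$meta$assay == "DNA", ]
  expect_error(filter_windows(rm$mat[, bad_meta$replicate_id], bad_meta),
               "missing assay/condition")
})

test_that("median-of-ratios normalization is depth-invariant", {
  set.seed(32)
  base <- rlnorm(300, log(50), 0.6)
  mat <- cbind(r1 = rpois(300, base), r2 = rpois(300, base),
               r3 = rpois(300, base))
  mat[mat == 0] <- 1L
  norm <- normalize_reporter(mat)
  # doubling one replicate's counts raises its scale factor relative to the
  # others by exactly 2, and shifts all abundances by one common constant,
  # so between-replicate contrasts are depth-invariant
  mat2 <- mat; mat2[, 2] <- 2L * mat[, 2]
  norm2 <- normalize_reporter(mat2)
  rel <- (norm2$scale_factors / norm$scale_factors)
  expect_equal(unname(rel[2] / rel[1]), 2, tolerance = 1e-8)
  shift <- norm2$abundance - norm$abundance
  expect_lt(max(abs(shift - mean(shift))), 0.06)
  # identical replicates get identical scale factors
  mat3 <- cbind(mat[, 1], mat[, 1], mat[, 3])
  norm3 <- normalize_reporter(mat3)
  expect_equal(norm3$scale_factors[1], norm3$scale_factors[2])
  # zero counts map to finite abundance through the 0.5 offset
  mat4 <- mat; mat4[1, 1] <- 0L
  expect_true(all(is.finite(normalize_reporter(mat4)$abundance)))
})

test_that("activity calls recover truth multipliers and the positivity rule", {
  rep <- simulate_reporter(800, frac_active = 0.1, frac_meth_dependent = 0,
                           activity_multiplier = 6, seed = 33)
  rm <- reporter_matrix(rep$counts)
  keep <- filter_windows(rm$mat, rm$meta)
  norm <- normalize_reporter(rm$mat[keep, , drop = FALSE])
  act <- test_activity(norm$abundance, rm$meta, n_perm = 5, seed = 33)
  truth <- rep$windows[as.integer(rownames(rm$mat)[keep]), ]
  # active-in-both-conditions windows dominate the called set
  called <- act$active
  expect_gt(sum(called & truth$is_active) / sum(truth$is_active), 0.8)
  expect_lt(sum(called & !truth$is_active) / max(1, sum(called)), 0.15)
  expect_true(all(act$active_class[called & truth$is_active] %in%
                    c("active_both", "active_methylated_only",
                      "active_unmethylated_only")))
  expect_gt(mean(act$active_class[called & truth$is_active] == "active_both"),
            0.5)

  # a window with RNA exactly equal to DNA has zero effect: not retained
  ab <- norm$abundance
  ab[1, ] <- 5
  act2 <- test_activity(ab, rm$meta, n_perm = 2, seed = 34)
  expect_false(act2$positive[1])
  expect_false(act2$active[1])
})

test_that("methylation dependence is detected with the right direction", {
  rep <- simulate_reporter(1000, frac_active = 0.08,
                           frac_meth_dependent = 0.08,
                           frac_unmeth_more_active = 1,
                           activity_multiplier = 6, seed = 35)
  rm <- reporter_matrix(rep$counts)
  keep <- filter_windows(rm$mat, rm$meta)
  norm <- normalize_reporter(rm$mat[keep, , drop = FALSE])
  act <- test_activity(norm$abundance, rm$meta, n_perm = 5, seed = 35)
  md <- test_methylation_dependence(norm$abundance, rm$meta,
                                    which(act$active), n_perm = 5,
                                    seed = 35)
  truth <- rep$windows[as.integer(rownames(rm$mat)[keep]), ]
  tmd <- truth$is_meth_dependent[md$window]
  expect_gt(mean(md$meth_dependent[tmd]), 0.8)
  expect_true(all(md$direction[md$meth_dependent & tmd] ==
                    "more_active_unmethylated"))

  expect_error(test_methylation_dependence(norm$abundance, rm$meta,
                                           integer(0)),
               "active set is empty")
})
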