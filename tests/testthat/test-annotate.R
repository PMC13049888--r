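# Genomic context: CpG-island detection, context assignment, enrichment,
# expression integration.

# Independent brute-force island detector: per-window substring counting,
# then per-base marking.
island_oracle <- function(seq, window = 100, min_len = 200, gc_min = 0.5,
                          oe_min = 0.6) {
  s <- toupper(seq)
  L <- nchar(s)
  if (L < window) return(data.frame(start = integer(0), end = integer(0)))
  marked <- logical(L)
  for (i in seq_len(L - window + 1)) {
    w <- substr(s, i, i + window - 1)
    nC <- lengths(regmatches(w, gregexpr("C", w, fixed = TRUE)))
    nG <- lengths(regmatches(w, gregexpr("G", w, fixed = TRUE)))
    nCpG <- lengths(regmatches(w, gregexpr("(?=CG)", w, perl = TRUE)))
    gc <- (nC + nG) / window
    oe <- if (nC > 0 && nG > 0) nCpG * window / (nC * nG) else 0
    if (gc > gc_min && oe > oe_min) marked[i:(i + window - 1)] <- TRUE
  }
  r <- rle(marked)
  e <- cumsum(r$lengths); st <- e - r$lengths + 1
  k <- which(r$values & r$lengths > min_len)
  data.frame(start = st[k], end = e[k])
}

random_seq <- function(L, gc = 0.5, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "T", "C", "G"), L, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

test_that("island detector finds CpG-dense runs and clips shores", {
  at <- paste(rep("AT", 5000), collapse = "")
  expect_equal(nrow(find_cpg_islands(at)$islands), 0)

  # 300 bp of CG repeats inside 10 kb of AT
  seq <- paste0(paste(rep("AT", 2500), collapse = ""),
                paste(rep("CG", 150), collapse = ""),
                paste(rep("AT", 2350), collapse = ""))
  res <- find_cpg_islands(seq)
  expect_equal(nrow(res$islands), 1)
  expect_lt(abs(res$islands$start[1] - 5001), 100)
  expect_lt(abs(res$islands$end[1] - 5300), 100)
  # shores flank the island without overlapping it
  expect_true(all(res$shores$end < res$islands$start[1] |
                    res$shores$start > res$islands$end[1]))

  # island at the sequence start: left shore clipped away or shortened
  seq2 <- paste0(paste(rep("CG", 200), collapse = ""),
                 paste(rep("AT", 3000), collapse = ""))
  res2 <- find_cpg_islands(seq2)
  expect_equal(res2$islands$start[1], 1)
  left <- res2$shores[res2$shores$end < res2$islands$end[1], ]
  expect_true(nrow(left) == 0)

  # case and trailing-N invariance
  seq3 <- paste0(seq, paste(rep("N", 500), collapse = ""))
  expect_identical(find_cpg_islands(tolower(seq))$islands, res$islands)
  expect_identical(find_cpg_islands(seq3)$islands, res$islands)
})

test_that("island detector matches the brute-force oracle", {
  for (i in 1:5) {
    seq <- random_seq(3000, gc = 0.55, seed = 100 + i)
    got <- find_cpg_islands(seq)$islands
    want <- island_oracle(seq)
    expect_equal(nrow(got), nrow(want))
    expect_equal(as.numeric(got$start), as.numeric(want$start))
    expect_equal(as.numeric(got$end), as.numeric(want$end))
  }
})

test_that("context assignment is strand-aware and multi-label", {
  genes <- data.frame(chrom = "chr1", start = 20000, end = 30000,
                      strand = "+", gene_id = "g1",
                      exon_starts = "20000,25000",
                      exon_ends = "21000,26000")
  genes <- rbind(genes,
                 data.frame(chrom = "chr1", start = 50000, end = 60000,
                            strand = "-", gene_id = "g2",
                            exon_starts = NA, exon_ends = NA))
  enh <- data.frame(chrom = "chr1", start = 40000, end = 40500)
  cpgs <- data.frame(chrom = "chr1",
                     pos = c(15000,  # 5 kb upstream of g1 (+): promoter
                             20500,  # inside exon 1 of g1
                             23000,  # gene body, not exon
                             40100,  # enhancer
                             62000,  # 2 kb "upstream" of g2 (-): promoter
                             49000)) # inside g2 body? no: upstream side
  ctx <- assign_context(cpgs, genes, enhancers = enh)
  f <- ctx$flags
  expect_true(f[1, "promoter"]); expect_false(f[1, "exon"])
  expect_true(f[2, "exon"]); expect_false(f[2, "promoter"])
  expect_true(f[3, "intron_utr"]); expect_false(f[3, "exon"])
  expect_true(f[4, "enhancer"])
  expect_true(f[5, "promoter"])
  expect_false(f[6, "promoter"])
  # gene windows assign nearby CpGs to genes
  expect_equal(ctx$gene_of[2], "g1")
  expect_equal(ctx$gene_of[4], "g1")  # within the widened 50 kb window

  bad <- cpgs; bad$chrom <- "chrX"
  expect_error(assign_context(bad, genes), "chromosome names")
})

test_that("context enrichment matches hypergeometric expectations", {
  set.seed(34)
  n <- 1000
  flags <- cbind(cpg_island = c(rep(TRUE, 200), rep(FALSE, 800)))
  # foreground built 100% inside islands
  fg <- 1:60
  res <- context_enrichment(fg, 1:n, flags)
  expect_gt(res$log2_or, 0)
  expect_lt(res$p, 1e-10)

  # random subsample: CI covers 0
  fg2 <- sample(n, 100)
  res2 <- context_enrichment(fg2, 1:n, flags)
  expect_true(res2$ci_lo <= 0 && res2$ci_hi >= 0)

  # the 2x2 table (10, 90, 50, 850) against fisher.test directly
  flags3 <- cbind(ctx = c(rep(TRUE, 10), rep(FALSE, 90),
                          rep(TRUE, 50), rep(FALSE, 850)))
  res3 <- context_enrichment(1:100, 1:1000, flags3)
  ft <- fisher.test(matrix(c(10, 90, 50, 850), 2, byrow = TRUE))
  expect_equal(res3$p, ft$p.value, tolerance = 1e-12)

  expect_error(context_enrichment(c(1, 2000), 1:1000, flags), "subset")
})

test_that("expression integration couples methylation to expression", {
  set.seed(35)
  n <- 400
  gene_of <- paste0("g", rep(1:80, each = 5))
  expr <- data.frame(gene_id = paste0("g", 1:80),
                     effect = rnorm(80, 0, 0.5),
                     significant = rep(c(TRUE, FALSE), 40))
  flags <- cbind(promoter = rep(TRUE, n))
  # methylation significance more likely at genes with big expression effects
  p_sig <- plogis(-2 + 4 * abs(expr$effect[match(gene_of, expr$gene_id)]))
  cpg_sig <- runif(n) < p_sig
  # negative coupling: methylation effect sign opposite to expression
  cpg_eff <- -0.3 * sign(expr$effect[match(gene_of, expr$gene_id)]) +
    rnorm(n, 0, 0.05)
  res <- expression_integration(cpg_sig, cpg_eff, gene_of, expr, flags)
  expect_gt(res$logistic$slope[1], 0)
  expect_lt(res$logistic$p[1], 0.05)
  expect_lt(res$concordance$log2_or[1], 0)

  # independence: slope CI covers zero
  res0 <- expression_integration(sample(cpg_sig), cpg_eff, gene_of, expr,
                                 flags)
  expect_gt(res0$logistic$p[1], 0.001)

  expect_warning(
    out <- expression_integration(cpg_sig, cpg_eff, rep(NA, n), expr, flags),
    "no CpG")
  expect_equal(nrow(out$logistic), 0)
})
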