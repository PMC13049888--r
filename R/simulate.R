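# Synthetic admixed cohorts with known ground truth.
#
# Two parental taxa ("yellow" and "anubis") diverge under a Balding-Nichols
# drift model; hybrids carry mosaic local-ancestry tracts from a two-state
# Markov process along each haplotype; methylation reads are generated per
# haplotype from allele-determined methylation probabilities with a
# beta-distributed individual effect (beta-binomial reads).

#' Simulation configuration
#'
#' Collects the generator's knobs with validation. Defaults describe a
#' desk-scale cohort: a few hundred individuals, one chromosome, RRBS-like
#' overdispersed coverage.
#'
#' @param n_individuals Number of hybrid individuals (each sampled once).
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_snps Number of SNPs (must be at least the number of meQTL CpGs).
#' @param n_cpgs Number of CpG sites.
#' @param divergence_F Balding-Nichols drift parameter in (0, 1).
#' @param admix_alpha Anubis admixture fraction in `[0, 1]`.
#' @param mean_tract_bp Mean local-ancestry tract length in bp.
#' @param mean_coverage Mean reads per CpG per individual.
#' @param coverage_size Negative-binomial size of the coverage distribution.
#' @param bb_dispersion Intraclass-correlation dispersion of individual
#'   methylation around the allele-determined mean (0 = pure binomial reads).
#' @param frac_meqtl Fraction of CpGs with a linked meQTL SNP within 100 bp.
#' @param frac_disrupted Fraction of meQTL CpGs whose alternate allele
#'   disrupts the CpG dinucleotide (forcing near-zero methylation).
#' @param effect_sd_logit SD of meQTL allelic effects on the logit scale.
#' @param read_length Read length in bp, controlling which reads co-observe a
#'   SNP and its CpG (allele-assignable reads).
#' @param seed Root seed; every stage draws from a named substream of it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 200, n_chromosomes = 1,
                       chrom_length = 2e6, n_snps = 500, n_cpgs = 400,
                       divergence_F = 0.28, admix_alpha = 0.37,
                       mean_tract_bp = 2e5, mean_coverage = 20,
                       coverage_size = 8, bb_dispersion = 0.02,
                       frac_meqtl = 0.3, frac_disrupted = 0.1,
                       effect_sd_logit = 1.5, read_length = 100,
                       seed = 1L) {
  cfg <- list(n_individuals = n_individuals, n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, n_snps = n_snps, n_cpgs = n_cpgs,
              divergence_F = divergence_F, admix_alpha = admix_alpha,
              mean_tract_bp = mean_tract_bp, mean_coverage = mean_coverage,
              coverage_size = coverage_size, bb_dispersion = bb_dispersion,
              frac_meqtl = frac_meqtl, frac_disrupted = frac_disrupted,
              effect_sd_logit = effect_sd_logit, read_length = read_length,
              seed = as.integer(seed))
  fracs <- c(admix_alpha = admix_alpha, frac_meqtl = frac_meqtl,
             frac_disrupted = frac_disrupted)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(divergence_F) || divergence_F <= 0 || divergence_F >= 1) {
    stop("divergence_F must be in (0, 1)", call. = FALSE)
  }
  if (chrom_length <= mean_tract_bp) {
    stop("chrom_length must exceed mean_tract_bp", call. = FALSE)
  }
  if (mean_coverage <= 0) stop("mean_coverage must be > 0", call. = FALSE)
  if (bb_dispersion < 0 || bb_dispersion >= 1) {
    stop("bb_dispersion must be in [0, 1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Parental allele frequencies under Balding-Nichols drift
#'
#' Each SNP's ancestral frequency is drawn uniformly on (0, 1); the two
#' parental population frequencies are then drawn independently from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`. SNPs with
#' `|p_anubis - p_yellow| >= 0.2` are flagged as ancestry-informative
#' markers.
#'
#' @param n_snps Number of SNPs.
#' @param divergence_F Drift parameter in (0, 1).
#' @param seed Integer seed.
#' @return data.frame with columns `snp_id`, `p_yellow`, `p_anubis`,
#'   `is_aim`.
#' @export
simulate_parental_frequencies <- function(n_snps, divergence_F, seed) {
  if (!is.finite(divergence_F) || divergence_F <= 0 || divergence_F >= 1) {
    stop("divergence_F must be finite and in (0, 1)", call. = FALSE)
  }
  set.seed(.substream(seed, "freqs"))
  p <- runif(n_snps)
  r <- (1 - divergence_F) / divergence_F
  p_y <- rbeta(n_snps, p * r, (1 - p) * r)
  p_a <- rbeta(n_snps, p * r, (1 - p) * r)
  data.frame(snp_id = seq_len(n_snps), p_yellow = p_y, p_anubis = p_a,
             is_aim = abs(p_a - p_y) >= 0.2)
}

#' Hudson's Fst for a pair of populations
#'
#' Ratio-of-averages estimator `mean((p1 - p2)^2) / mean(p1 (1 - p2) +
#' p2 (1 - p1))`, whose expectation under Balding-Nichols drift equals the
#' drift parameter.
#'
#' @param p1,p2 Allele-frequency vectors.
#' @return Scalar Fst estimate.
#' @export
fst_hudson <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

#' Lay out SNP and CpG positions
#'
#' CpG positions are uniform along each chromosome. A fraction
#' `frac_meqtl` of CpGs gets a dedicated meQTL SNP within 100 bp (disrupted
#' ones at the CpG dinucleotide itself); remaining SNPs are placed uniformly.
#'
#' @param config A [sim_config()].
#' @return List with `loci` (data.frame chrom, pos, type, id) and `pairs`
#'   (data.frame cpg_id, snp_id, distance, disrupted).
#' @export
simulate_loci <- function(config) {
  set.seed(.substream(config$seed, "truth") + 7L)
  n_meqtl <- round(config$frac_meqtl * config$n_cpgs)
  if (config$n_snps < n_meqtl) {
    stop("n_snps must be at least the number of meQTL CpGs", call. = FALSE)
  }
  n_dis <- round(config$frac_disrupted * n_meqtl)
  cpg <- data.frame(
    chrom = sample(config$n_chromosomes, config$n_cpgs, replace = TRUE),
    pos = sample(200:(config$chrom_length - 200), config$n_cpgs),
    type = "cpg", id = seq_len(config$n_cpgs))
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  cpg$id <- seq_len(config$n_cpgs)
  meqtl_cpg <- sort(sample(config$n_cpgs, n_meqtl))
  disrupted <- rep(FALSE, n_meqtl)
  if (n_dis > 0) disrupted[sample(n_meqtl, n_dis)] <- TRUE
  dist <- ifelse(disrupted, sample(0:1, n_meqtl, replace = TRUE),
                 sample(2:100, n_meqtl, replace = TRUE))
  snp_pos <- cpg$pos[meqtl_cpg] + dist * sample(c(-1L, 1L), n_meqtl,
                                                replace = TRUE)
  snp_pos[disrupted] <- cpg$pos[meqtl_cpg][disrupted] + dist[disrupted]
  n_bg <- config$n_snps - n_meqtl
  snp <- data.frame(
    chrom = c(cpg$chrom[meqtl_cpg],
              sample(config$n_chromosomes, n_bg, replace = TRUE)),
    pos = c(snp_pos,
            sample(200:(config$chrom_length - 200), n_bg)),
    type = "snp", id = seq_len(config$n_snps))
  pairs <- data.frame(cpg_id = meqtl_cpg, snp_id = seq_len(n_meqtl),
                      distance = abs(snp$pos[seq_len(n_meqtl)] -
                                     cpg$pos[meqtl_cpg]),
                      disrupted = disrupted)
  loci <- rbind(cpg, snp)
  list(loci = loci, pairs = pairs)
}

#' Simulate mosaic local-ancestry tracts
#'
#' Each haplotype follows a two-state Markov (alternating-exponential)
#' process along the chromosome with stationary anubis probability
#' `admix_alpha` and mean segment length `mean_tract_bp`; the per-individual
#' global ancestry is the mean dosage over loci divided by two.
#'
#' @param config A [sim_config()].
#' @param loci data.frame with columns `chrom`, `pos` (as from
#'   [simulate_loci()]).
#' @return List of class `"ancestry_panel"`: `dosage` (loci x individuals,
#'   anubis allele count 0/1/2), `hap1`/`hap2` (haplotype ancestry 0/1),
#'   `global` (per-individual fraction), `tracts` (data.frame chrom, start,
#'   end, individual, haplotype, state; 0-based half-open), `loci`.
#' @export
simulate_ancestry <- function(config, loci) {
  set.seed(.substream(config$seed, "ancestry"))
  alpha <- config$admix_alpha
  n <- config$n_individuals
  L <- config$chrom_length
  nl <- nrow(loci)
  hap <- list(matrix(0L, nl, n), matrix(0L, nl, n))
  tracts <- vector("list", 2L * n * config$n_chromosomes)
  ti <- 0L
  mean_a <- 2 * alpha * config$mean_tract_bp
  mean_y <- 2 * (1 - alpha) * config$mean_tract_bp
  for (ind in seq_len(n)) {
    for (h in 1:2) {
      for (chr in seq_len(config$n_chromosomes)) {
        idx <- which(loci$chrom == chr)
        if (alpha == 0 || alpha == 1) {
          st <- as.integer(alpha)
          hap[[h]][idx, ind] <- st
          ti <- ti + 1L
          tracts[[ti]] <- data.frame(chrom = chr, start = 0, end = L,
                                     individual = ind, haplotype = h,
                                     state = st)
          next
        }
        state <- rbinom(1L, 1L, alpha)
        pos <- 0
        starts <- ends <- numeric(0)
        states <- integer(0)
        while (pos < L) {
          len <- rexp(1L, 1 / if (state == 1L) mean_a else mean_y)
          end <- min(pos + len, L)
          starts <- c(starts, pos); ends <- c(ends, end)
          states <- c(states, state)
          pos <- end
          state <- 1L - state
        }
        ti <- ti + 1L
        tracts[[ti]] <- data.frame(chrom = chr, start = starts, end = ends,
                                   individual = ind, haplotype = h,
                                   state = states)
        if (length(idx)) {
          seg <- findInterval(loci$pos[idx], starts)
          hap[[h]][idx, ind] <- states[seg]
        }
      }
    }
  }
  dosage <- hap[[1L]] + hap[[2L]]
  structure(list(dosage = dosage, hap1 = hap[[1L]], hap2 = hap[[2L]],
                 global = colMeans(dosage) / 2,
                 tracts = do.call(rbind, tracts[seq_len(ti)]), loci = loci),
            class = "ancestry_panel")
}

#' Simulate genotypes on top of local ancestry
#'
#' Each haplotype's allele at a SNP is Bernoulli with the parental
#' alternate-allele frequency matching that haplotype's local ancestry;
#' genotype is the sum of the two haplotype alleles.
#'
#' @param panel An `ancestry_panel` from [simulate_ancestry()].
#' @param freqs Parental frequencies, one row per SNP locus (as from
#'   [simulate_parental_frequencies()]); `p_*` is the alternate-allele
#'   frequency.
#' @param seed Integer seed.
#' @return List of class `"genotypes"`: `geno` (SNPs x individuals dosage of
#'   the alternate allele), `hap1`/`hap2` allele matrices, `snp_rows` (rows
#'   of `panel$loci` used).
#' @export
simulate_genotypes <- function(panel, freqs, seed) {
  snp_rows <- which(panel$loci$type == "snp")
  if (length(snp_rows) != nrow(freqs)) {
    stop("panel SNP loci and frequency table are misaligned", call. = FALSE)
  }
  set.seed(.substream(seed, "genotypes"))
  n <- ncol(panel$dosage)
  m <- length(snp_rows)
  draw <- function(anc) {
    p <- ifelse(anc == 1L, freqs$p_anubis, freqs$p_yellow)
    matrix(rbinom(m * n, 1L, p), m, n)
  }
  a1 <- draw(panel$hap1[snp_rows, , drop = FALSE])
  a2 <- draw(panel$hap2[snp_rows, , drop = FALSE])
  structure(list(geno = a1 + a2, hap1 = a1, hap2 = a2, snp_rows = snp_rows),
            class = "genotypes")
}

#' Draw per-CpG ground truth
#'
#' Baseline methylation logits are uniform over the intermediate range;
#' meQTL CpGs get an allelic effect drawn from a normal on the logit scale,
#' and disrupted CpGs force the alternate allele's methylation to ~0.01.
#' The true per-allele proportion-scale effect is `m_alt - m_ref` and the
#' true ancestry effect is that effect times the parental frequency
#' difference at the linked SNP.
#'
#' @param config A [sim_config()].
#' @param layout Output of [simulate_loci()].
#' @param freqs Parental frequencies for the SNPs in `layout`.
#' @return data.frame, one row per CpG: `cpg_id`, `baseline_logit`,
#'   `snp_id` (NA when unlinked), `m_ref`, `m_alt`, `true_delta`,
#'   `is_disrupted`, `true_ancestry_effect`.
#' @export
simulate_truth <- function(config, layout, freqs) {
  set.seed(.substream(config$seed, "truth"))
  n_cpgs <- config$n_cpgs
  base <- runif(n_cpgs, qlogis(0.15), qlogis(0.85))
  truth <- data.frame(cpg_id = seq_len(n_cpgs), baseline_logit = base,
                      snp_id = NA_integer_, m_ref = plogis(base),
                      m_alt = plogis(base), true_delta = 0,
                      is_disrupted = FALSE, true_ancestry_effect = 0)
  pr <- layout$pairs
  if (nrow(pr)) {
    eff <- rnorm(nrow(pr), 0, config$effect_sd_logit)
    truth$snp_id[pr$cpg_id] <- pr$snp_id
    truth$m_alt[pr$cpg_id] <- plogis(base[pr$cpg_id] + eff)
    truth$m_alt[pr$cpg_id[pr$disrupted]] <- 0.01
    truth$is_disrupted[pr$cpg_id] <- pr$disrupted
    truth$true_delta <- truth$m_alt - truth$m_ref
    dp <- freqs$p_anubis[truth$snp_id[pr$cpg_id]] -
      freqs$p_yellow[truth$snp_id[pr$cpg_id]]
    truth$true_ancestry_effect[pr$cpg_id] <- truth$true_delta[pr$cpg_id] * dp
  }
  truth
}

# Beta draw around mean m with intraclass correlation phi; degenerate at
# phi = 0 or m on the boundary.
.rbeta_icc <- function(k, m, phi) {
  if (phi == 0) return(rep_len(m, k))
  out <- rep_len(m, k)
  inner <- m > 0 & m < 1
  if (any(inner)) {
    r <- (1 - phi) / phi
    mi <- rep_len(m, k)[inner]
    out[inner] <- rbeta(sum(inner), mi * r, (1 - mi) * r)
  }
  out
}

#' Simulate methylation read counts
#'
#' Per individual and CpG, total coverage is negative-binomial; each read is
#' assigned to one of the two haplotypes uniformly; its methylation state is
#' Bernoulli with that haplotype allele's methylation probability perturbed
#' by a beta-distributed individual effect (`bb_dispersion`). For CpGs with
#' a linked SNP, reads co-observing the SNP (probability
#' `1 - distance / read_length`) are allele-assignable, and heterozygotes'
#' allele-specific counts are emitted.
#'
#' @param genotypes A `genotypes` object.
#' @param truth Output of [simulate_truth()].
#' @param panel The `ancestry_panel` used to generate the genotypes.
#' @param layout Output of [simulate_loci()].
#' @param config A [sim_config()].
#' @return List of class `"meth_counts"`: `meth`, `total` (CpGs x
#'   individuals), `allele_specific` (data.frame cpg_id, individual,
#'   meth_ref, total_ref, meth_alt, total_alt for heterozygotes at paired
#'   CpGs), `cpg_loci`.
#' @export
simulate_methylation <- function(genotypes, truth, panel, layout, config) {
  set.seed(.substream(config$seed, "methylation"))
  n <- config$n_individuals
  n_cpgs <- config$n_cpgs
  cpg_rows <- which(panel$loci$type == "cpg")
  meth <- total <- matrix(0L, n_cpgs, n)
  as_list <- list()
  pair_by_cpg <- rep(NA_integer_, n_cpgs)
  pair_by_cpg[layout$pairs$cpg_id] <- seq_len(nrow(layout$pairs))
  phi <- config$bb_dispersion
  for (j in seq_len(n_cpgs)) {
    tot <- rnbinom(n, mu = config$mean_coverage, size = config$coverage_size)
    t1 <- rbinom(n, tot, 0.5)
    t2 <- tot - t1
    pi_idx <- pair_by_cpg[j]
    if (is.na(pi_idx)) {
      m1 <- m2 <- rep(truth$m_ref[j], n)
    } else {
      sid <- truth$snp_id[j]
      a1 <- genotypes$hap1[sid, ]
      a2 <- genotypes$hap2[sid, ]
      m1 <- ifelse(a1 == 1L, truth$m_alt[j], truth$m_ref[j])
      m2 <- ifelse(a2 == 1L, truth$m_alt[j], truth$m_ref[j])
    }
    p1 <- .rbeta_icc(n, m1, phi)
    p2 <- .rbeta_icc(n, m2, phi)
    k1 <- rbinom(n, t1, p1)
    k2 <- rbinom(n, t2, p2)
    meth[j, ] <- k1 + k2
    total[j, ] <- tot
    if (!is.na(pi_idx)) {
      d <- layout$pairs$distance[pi_idx]
      p_assign <- max(0, 1 - d / config$read_length)
      het <- which(genotypes$geno[truth$snp_id[j], ] == 1L)
      if (length(het) && p_assign > 0) {
        # haplotype 1 carries ref or alt depending on its allele
        tr <- ta <- mr <- ma <- integer(length(het))
        for (ii in seq_along(het)) {
          i <- het[ii]
          alt_first <- genotypes$hap1[truth$snp_id[j], i] == 1L
          t_alt <- if (alt_first) t1[i] else t2[i]
          t_ref <- if (alt_first) t2[i] else t1[i]
          k_alt <- if (alt_first) k1[i] else k2[i]
          k_ref <- if (alt_first) k2[i] else k1[i]
          ta[ii] <- rbinom(1L, t_alt, p_assign)
          tr[ii] <- rbinom(1L, t_ref, p_assign)
          # assignable reads are an exchangeable subset of the haplotype
          ma[ii] <- if (t_alt > 0) rhyper(1L, k_alt, t_alt - k_alt, ta[ii])
                    else 0L
          mr[ii] <- if (t_ref > 0) rhyper(1L, k_ref, t_ref - k_ref, tr[ii])
                    else 0L
        }
        as_list[[length(as_list) + 1L]] <- data.frame(
          cpg_id = j, individual = het, meth_ref = mr, total_ref = tr,
          meth_alt = ma, total_alt = ta)
      }
    }
  }
  if (all(total == 0)) {
    warning("zero coverage everywhere: degenerate output")
  }
  allele_specific <- if (length(as_list)) do.call(rbind, as_list) else
    data.frame(cpg_id = integer(0), individual = integer(0),
               meth_ref = integer(0), total_ref = integer(0),
               meth_alt = integer(0), total_alt = integer(0))
  structure(list(meth = meth, total = total,
                 allele_specific = allele_specific,
                 cpg_loci = panel$loci[cpg_rows, ]),
            class = "meth_counts")
}

#' Simulate a full admixed cohort
#'
#' Convenience wrapper running the generator end to end: parental
#' frequencies, locus layout, ancestry tracts, genotypes, ground truth and
#' methylation counts.
#'
#' @param config A [sim_config()].
#' @return List with elements `config`, `freqs`, `layout`, `panel`,
#'   `genotypes`, `truth`, `counts`.
#' @export
simulate_cohort <- function(config) {
  freqs <- simulate_parental_frequencies(config$n_snps, config$divergence_F,
                                         config$seed)
  layout <- simulate_loci(config)
  panel <- simulate_ancestry(config, layout$loci)
  genotypes <- simulate_genotypes(panel, freqs, config$seed)
  truth <- simulate_truth(config, layout, freqs)
  counts <- simulate_methylation(genotypes, truth, panel, layout, config)
  list(config = config, freqs = freqs, layout = layout, panel = panel,
       genotypes = genotypes, truth = truth, counts = counts)
}

#' Simulate reporter-assay (mSTARR-style) DNA/RNA replicate counts
#'
#' DNA counts follow a negative-binomial library model; RNA counts have the
#' DNA expectation scaled by a global RNA/DNA depth ratio and a per-window
#' activity multiplier: 1 for inactive windows, `activity_multiplier` for
#' active ones, and condition-specific for methylation-dependent windows
#' (the unmethylated condition more active for a configurable majority).
#'
#' @param n_windows Number of 500-bp windows.
#' @param n_replicates Replicates per assay per condition.
#' @param frac_active Fraction of windows with regulatory activity.
#' @param frac_meth_dependent Fraction with methylation-dependent activity
#'   (must not exceed `frac_active`).
#' @param frac_unmeth_more_active Among methylation-dependent windows, the
#'   fraction more active in the unmethylated condition.
#' @param activity_multiplier RNA amplification of active windows.
#' @param dna_mean,dna_size Negative-binomial DNA coverage parameters.
#' @param rna_scale Global RNA/DNA depth ratio (< 1: most windows show fewer
#'   RNA than DNA reads, as in real assays).
#' @param seed Integer seed.
#' @return List of class `"reporter_counts"`: `counts` (long data.frame
#'   window_id, replicate_id, assay, condition, count), `windows` (truth
#'   labels), `meta` (replicate metadata with DNA/RNA pairing).
#' @export
simulate_reporter <- function(n_windows = 2000, n_replicates = 6,
                              frac_active = 0.05,
                              frac_meth_dependent = 0.04,
                              frac_unmeth_more_active = 0.87,
                              activity_multiplier = 6, dna_mean = 60,
                              dna_size = 5, rna_scale = 0.3, seed = 1L) {
  if (frac_meth_dependent > frac_active) {
    stop("frac_meth_dependent cannot exceed frac_active", call. = FALSE)
  }
  set.seed(.substream(seed, "reporter"))
  n_active <- round(n_windows * frac_active)
  n_md <- round(n_windows * frac_meth_dependent)
  is_active <- rep(FALSE, n_windows)
  if (n_active > 0) is_active[sample(n_windows, n_active)] <- TRUE
  act_idx <- which(is_active)
  is_md <- rep(FALSE, n_windows)
  if (n_md > 0) is_md[sample(act_idx, n_md)] <- TRUE
  dir_unmeth <- rep(NA, n_windows)
  dir_unmeth[is_md] <- runif(n_md) < frac_unmeth_more_active

  mult_meth <- mult_unmeth <- rep(1, n_windows)
  plain_active <- is_active & !is_md
  mult_meth[plain_active] <- activity_multiplier
  mult_unmeth[plain_active] <- activity_multiplier
  mult_unmeth[is_md & dir_unmeth] <- activity_multiplier
  mult_meth[is_md & !dir_unmeth] <- activity_multiplier

  base <- rlnorm(n_windows, log(dna_mean), 0.5)
  conds <- c("methylated", "unmethylated")
  meta <- expand.grid(assay = c("DNA", "RNA"), condition = conds,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  meta$replicate_id <- sprintf("%s_%s_r%d", meta$assay,
                               substr(meta$condition, 1, 5), meta$replicate)
  libfac <- rlnorm(nrow(meta), 0, 0.15)
  rows <- vector("list", nrow(meta))
  for (k in seq_len(nrow(meta))) {
    mult <- if (meta$assay[k] == "DNA") rep(1, n_windows)
            else rna_scale * (if (meta$condition[k] == "methylated")
                              mult_meth else mult_unmeth)
    mu <- base * libfac[k] * mult
    rows[[k]] <- data.frame(window_id = seq_len(n_windows),
                            replicate_id = meta$replicate_id[k],
                            assay = meta$assay[k],
                            condition = meta$condition[k],
                            count = rnbinom(n_windows, mu = mu,
                                            size = dna_size))
  }
  windows <- data.frame(
    window_id = seq_len(n_windows), chrom = 1L,
    start = (seq_len(n_windows) - 1L) * 500L,
    end = seq_len(n_windows) * 500L,
    is_active = is_active, is_meth_dependent = is_md,
    more_active_unmethylated = dir_unmeth,
    mult_meth = mult_meth, mult_unmeth = mult_unmeth)
  structure(list(counts = do.call(rbind, rows), windows = windows,
                 meta = meta[, c("replicate_id", "assay", "condition",
                                 "replicate")]),
            class = "reporter_counts")
}
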