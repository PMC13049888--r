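# End-to-end orchestration over synthetic inputs, with filter bookkeeping
# and a provenance manifest.

#' Collapse repeat samples to one column per individual
#'
#' Methylated and total counts are summed across an individual's samples at
#' every site. A sample mapped to more than one individual is an input
#' error.
#'
#' @param counts List with `meth`/`total` matrices whose columns are
#'   samples, with column names matching `sample_to_individual$sample`.
#' @param sample_to_individual data.frame with columns `sample`,
#'   `individual`.
#' @return List with `meth`/`total` matrices, one column per individual.
#' @export
collapse_repeat_samples <- function(counts, sample_to_individual) {
  map <- unique(sample_to_individual[, c("sample", "individual")])
  if (anyDuplicated(map$sample)) {
    dup <- unique(map$sample[duplicated(map$sample)])
    stop("sample mapped to more than one individual: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  samples <- colnames(counts$meth)
  if (is.null(samples)) {
    stop("count matrices need sample column names", call. = FALSE)
  }
  ind <- map$individual[match(samples, map$sample)]
  if (any(is.na(ind))) {
    stop("unmapped samples: ",
         paste(samples[is.na(ind)], collapse = ", "), call. = FALSE)
  }
  inds <- unique(ind)
  agg <- function(M) {
    out <- vapply(inds, function(i)
      rowSums(M[, ind == i, drop = FALSE]), numeric(nrow(M)))
    out <- matrix(out, nrow = nrow(M), dimnames = list(NULL, inds))
    out
  }
  list(meth = agg(counts$meth), total = agg(counts$total))
}

#' Pipeline configuration
#'
#' Thresholds default to the analysis conventions used throughout the
#' package: 10% FDR, nominal species p of 0.01, meQTL MAF 0.05, 100 bp pair
#' distance, at least 10 individuals per ancestry state, mean methylation in
#' `[0.1, 0.9]`, reporter DNA median coverage strictly above 4.
#'
#' @param sim A [sim_config()] for the synthetic cohort.
#' @param n_perm Permutations per scan.
#' @param fdr FDR threshold.
#' @param species_p Nominal p threshold for species differences.
#' @param maf_min meQTL minor-allele-frequency threshold.
#' @param max_dist meQTL pair distance in bp.
#' @param min_per_state Minimum individuals per ancestry state.
#' @param mean_range Mean-methylation bounds.
#' @param dna_median Reporter DNA median-coverage threshold.
#' @param reporter_windows Number of reporter windows to simulate.
#' @param seed Root seed (mandatory: every stochastic stage derives its
#'   substream from it).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), n_perm = 5, fdr = 0.10,
                            species_p = 0.01, maf_min = 0.05,
                            max_dist = 100, min_per_state = 10,
                            mean_range = c(0.1, 0.9), dna_median = 4,
                            reporter_windows = 500, seed = 1L) {
  stopifnot(fdr > 0, fdr < 1, species_p > 0, species_p < 1,
            maf_min >= 0, maf_min < 0.5, max_dist > 0, min_per_state >= 1,
            mean_range[1] >= 0, mean_range[2] <= 1,
            mean_range[1] < mean_range[2])
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, n_perm = n_perm, fdr = fdr,
                 species_p = species_p, maf_min = maf_min,
                 max_dist = max_dist, min_per_state = min_per_state,
                 mean_range = mean_range, dna_median = dna_median,
                 reporter_windows = reporter_windows,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, runs the ancestry scan, meQTL mapping, composition
#' comparison, variance analysis and reporter-assay calls in dependency
#' order, writes every stage's table as TSV under `out_dir`, and records a
#' provenance manifest (config values, seed, per-stage row counts at every
#' filter). Identical config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   config = utils::modifyList(unclass(config)[-1],
                                              list(sim = unclass(config$sim))))
  coh <- simulate_cohort(config$sim)
  write_counts_tsv(coh$counts, file.path(out_dir, "meth_counts.tsv"))
  snp_loci <- coh$panel$loci[coh$panel$loci$type == "snp", ]
  write_genotypes_vcf(coh$genotypes, snp_loci,
                      file.path(out_dir, "genotypes.vcf"))
  write_ancestry_bed(coh$panel, file.path(out_dir, "ancestry_tracts.bed"))
  write_truth_tsv(coh$truth, file.path(out_dir, "truth_cpgs.tsv"))

  sites <- filter_sites(coh$counts, coh$panel,
                        mean_range = config$mean_range,
                        min_per_state = config$min_per_state)
  manifest$ancestry_scan <- list(input = nrow(coh$counts$meth),
                                 retained = length(sites))
  scan <- ancestry_scan(coh$counts, coh$panel, n_perm = config$n_perm,
                        seed = config$seed, sites = sites)
  write_truth_tsv(as.data.frame(scan),
                  file.path(out_dir, "ancestry_scan.tsv"))

  built <- build_pairs(coh$genotypes, coh$counts, coh$layout$pairs,
                       max_dist = config$max_dist,
                       maf_min = config$maf_min,
                       mean_range = config$mean_range)
  manifest$meqtl <- attr(built, "filter_log")
  meqtl <- meqtl_scan(built, n_perm = config$n_perm, seed = config$seed)
  write_truth_tsv(as.data.frame(meqtl), file.path(out_dir, "meqtl.tsv"))

  comp_idx <- match(meqtl$cpg_id, scan$site)
  usable <- !is.na(comp_idx) & meqtl$converged & scan$converged[comp_idx]
  records <- composition_records(
    delta = meqtl$delta[usable],
    p_yellow = coh$freqs$p_yellow[meqtl$snp_id[usable]],
    p_anubis = coh$freqs$p_anubis[meqtl$snp_id[usable]],
    observed = scan$effect_local[comp_idx[usable]] / 2,
    cpg_id = meqtl$cpg_id[usable],
    disrupted = meqtl$disrupted[usable])
  write_truth_tsv(as.data.frame(records),
                  file.path(out_dir, "composition.tsv"))
  comp <- if (nrow(records) >= 3) compare_composition(records) else NULL
  manifest$composition <- list(records = nrow(records))

  dosage_snp <- coh$panel$dosage[coh$genotypes$snp_rows, , drop = FALSE]
  shift <- maf_shift(coh$genotypes, dosage_snp)
  dosage_cpg <- .cpg_dosage(coh$panel, nrow(coh$counts$meth))
  gain <- sd_gain(coh$counts, dosage_cpg)
  write_truth_tsv(shift$per_snp, file.path(out_dir, "maf_shift.tsv"))
  write_truth_tsv(gain$per_site, file.path(out_dir, "sd_gain.tsv"))
  manifest$variance <- list(snps = nrow(shift$per_snp),
                            skipped = shift$skipped)

  rep_sim <- simulate_reporter(n_windows = config$reporter_windows,
                               seed = config$seed)
  write_reporter_tsv(rep_sim, file.path(out_dir, "reporter_counts.tsv"))
  rm <- reporter_matrix(rep_sim$counts)
  wkeep <- filter_windows(rm$mat, rm$meta, dna_median = config$dna_median)
  manifest$mstarr <- attr(wkeep, "filter_log")
  norm <- normalize_reporter(rm$mat[wkeep, , drop = FALSE])
  act <- test_activity(norm$abundance, rm$meta, n_perm = config$n_perm,
                       seed = config$seed, fdr = config$fdr)
  act$window_id <- as.integer(rownames(rm$mat)[wkeep])
  write_truth_tsv(as.data.frame(act), file.path(out_dir, "mstarr_activity.tsv"))
  md <- NULL
  if (any(act$active)) {
    md <- test_methylation_dependence(norm$abundance, rm$meta,
                                      which(act$active),
                                      n_perm = config$n_perm,
                                      seed = config$seed, fdr = config$fdr)
    md$window_id <- act$window_id[md$window]
    write_truth_tsv(as.data.frame(md),
                    file.path(out_dir, "mstarr_meth_dependence.tsv"))
  }
  manifest$mstarr$active <- sum(act$active)

  man_lines <- c("pipeline manifest",
                 paste0("seed\t", config$seed),
                 vapply(names(manifest), function(nm)
                   paste0(nm, "\t", paste(deparse(manifest[[nm]]),
                                          collapse = " ")),
                   character(1)))
  writeLines(man_lines, file.path(out_dir, "manifest.txt"))
  invisible(list(cohort = coh, scan = scan, meqtl = meqtl,
                 composition = comp, maf_shift = shift, sd_gain = gain,
                 activity = act, meth_dependence = md,
                 manifest = manifest))
}
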