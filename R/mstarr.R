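# Regulatory-activity and methylation-dependence calls from reporter-assay
# DNA/RNA replicate counts (mSTARR-seq style).

#' Reshape long reporter counts to a window x replicate matrix
#'
#' @param counts Long data.frame with `window_id`, `replicate_id`, `assay`,
#'   `condition`, `count` (as written by [simulate_reporter()]).
#' @return List: `mat` (windows x replicates), `meta` (one row per
#'   replicate: `replicate_id`, `assay`, `condition`, `pair` index pairing
#'   each DNA replicate with its RNA replicate within condition).
#' @export
reporter_matrix <- function(counts) {
  need <- c("window_id", "replicate_id", "assay", "condition", "count")
  if (!all(need %in% names(counts))) {
    stop("reporter counts need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  reps <- unique(counts[, c("replicate_id", "assay", "condition")])
  if (nrow(unique(reps[, c("assay", "condition")])) < 4) {
    stop("missing assay/condition combination", call. = FALSE)
  }
  wins <- sort(unique(counts$window_id))
  mat <- matrix(0L, length(wins), nrow(reps),
                dimnames = list(wins, reps$replicate_id))
  mat[cbind(match(counts$window_id, wins),
            match(counts$replicate_id, reps$replicate_id))] <- counts$count
  # pair DNA and RNA replicates within condition by order of appearance
  reps$pair <- NA_integer_
  for (cond in unique(reps$condition)) {
    for (a in c("DNA", "RNA")) {
      idx <- which(reps$condition == cond & reps$assay == a)
      reps$pair[idx] <- seq_along(idx) +
        1000L * match(cond, unique(reps$condition))
    }
  }
  list(mat = mat, meta = reps)
}

#' Window filters for reporter analysis
#'
#' Retains windows with (i) median coverage strictly greater than
#' `dna_median` in both methylated and unmethylated DNA samples, (ii)
#' non-zero DNA counts in at least half of the DNA replicates of each
#' condition, and (iii) non-zero RNA counts in at least half of the RNA
#' replicates of either condition. Per-rule loss counts are attached as
#' attribute `filter_log`.
#'
#' @param mat Window x replicate count matrix.
#' @param meta Replicate metadata (see [reporter_matrix()]).
#' @param dna_median DNA median-coverage threshold (strict).
#' @return Integer vector of retained window (row) indices.
#' @export
filter_windows <- function(mat, meta, dna_median = 4) {
  conds <- unique(meta$condition)
  if (length(conds) < 2 || !all(c("DNA", "RNA") %in% meta$assay)) {
    stop("missing assay/condition combination", call. = FALSE)
  }
  sel <- function(a, cond) which(meta$assay == a & meta$condition == cond)
  dna1 <- mat[, sel("DNA", conds[1]), drop = FALSE]
  dna2 <- mat[, sel("DNA", conds[2]), drop = FALSE]
  rna1 <- mat[, sel("RNA", conds[1]), drop = FALSE]
  rna2 <- mat[, sel("RNA", conds[2]), drop = FALSE]
  med1 <- apply(dna1, 1, stats::median)
  med2 <- apply(dna2, 1, stats::median)
  r_i <- med1 > dna_median & med2 > dna_median
  r_ii <- rowMeans(dna1 > 0) >= 0.5 & rowMeans(dna2 > 0) >= 0.5
  r_iii <- rowMeans(rna1 > 0) >= 0.5 | rowMeans(rna2 > 0) >= 0.5
  keep <- which(r_i & r_ii & r_iii)
  attr(keep, "filter_log") <- list(
    input = nrow(mat),
    dna_median = sum(r_i), dna_presence = sum(r_i & r_ii),
    rna_presence = length(keep))
  keep
}

#' Median-of-ratios normalization to log2 abundance
#'
#' Computes per-replicate scale factors by the median of each replicate's
#' count ratios against the geometric-mean pseudo-reference (over windows
#' observed in every replicate), then returns
#' `log2((count + 0.5) / scale)` with the scale factors rescaled so their
#' geometric mean preserves the overall count magnitude.
#'
#' @param mat Filtered window x replicate count matrix.
#' @return List: `abundance` (log2 matrix), `scale_factors`, `excluded`
#'   (replicates with all-zero counts, dropped with a warning).
#' @export
normalize_reporter <- function(mat) {
  allzero <- colSums(mat) == 0
  if (any(allzero)) {
    warning("dropping all-zero replicates: ",
            paste(colnames(mat)[allzero], collapse = ", "))
    mat <- mat[, !allzero, drop = FALSE]
  }
  pos <- rowSums(mat == 0) == 0
  if (!any(pos)) stop("no window observed in all replicates", call. = FALSE)
  ref <- exp(rowMeans(log(mat[pos, , drop = FALSE])))
  sf <- apply(mat[pos, , drop = FALSE], 2, function(cnt)
    stats::median(cnt / ref))
  # keep abundances on a counts-like scale
  sf_scaled <- sf / exp(mean(log(sf)))
  ab <- log2(sweep(mat + 0.5, 2, sf_scaled, "/"))
  list(abundance = ab, scale_factors = sf, excluded = which(allzero))
}

# Per-condition RNA-vs-DNA contrast with a pooled-variance test, vectorized
# over windows. Returns effect, se, df, p per condition plus the interaction.
.activity_stats <- function(ab, meta) {
  conds <- unique(meta$condition)
  groups <- list()
  for (cond in conds) {
    for (a in c("DNA", "RNA")) {
      groups[[paste(a, cond, sep = ".")]] <-
        which(meta$assay == a & meta$condition == cond)
    }
  }
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, function(ix) rowMeans(ab[, ix, drop = FALSE]),
                  numeric(nrow(ab)))
  ssw <- 0
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    ssw <- ssw + rowSums((ab[, ix, drop = FALSE] - means[, g])^2)
  }
  df <- sum(ns) - length(groups)
  s2 <- ssw / df
  eff <- se <- matrix(NA_real_, nrow(ab), 2,
                      dimnames = list(NULL, conds))
  for (ci in 1:2) {
    rna <- paste("RNA", conds[ci], sep = ".")
    dna <- paste("DNA", conds[ci], sep = ".")
    eff[, ci] <- means[, rna] - means[, dna]
    se[, ci] <- sqrt(s2 * (1 / ns[[rna]] + 1 / ns[[dna]]))
  }
  p <- 2 * pt(-abs(eff / se), df)
  inter_eff <- eff[, "unmethylated"] - eff[, "methylated"]
  inter_se <- sqrt(s2 * sum(1 / ns))
  inter_p <- 2 * pt(-abs(inter_eff / inter_se), df)
  list(effect = eff, p = p, df = df,
       interaction_effect = inter_eff, interaction_p = inter_p)
}

#' Test windows for regulatory activity
#'
#' Per condition, contrasts mean RNA abundance against mean DNA abundance
#' with a pooled-variance test. Only windows with a positive RNA-vs-DNA
#' effect in at least one condition proceed to FDR estimation; the
#' permutation null swaps RNA/DNA labels within each replicate pair, and
#' each permutation's p-value pool is subsampled to the observed number of
#' positive-effect windows before q-value estimation.
#'
#' @param ab Normalized log2 abundance matrix (from [normalize_reporter()]).
#' @param meta Replicate metadata with `pair` indices.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param fdr Activity threshold on q.
#' @return data.frame of class `"activity_call"`: per window
#'   `effect_meth`, `effect_unmeth`, `p_meth`, `p_unmeth`, `q_meth`,
#'   `q_unmeth`, `positive` (retained by the positivity rule), `active`
#'   (q < `fdr` in >= 1 condition with positive effect), `active_class`.
#' @export
test_activity <- function(ab, meta, n_perm = 10, seed = 1L, fdr = 0.10) {
  if (any(table(meta$assay, meta$condition) < 2)) {
    stop("need at least 2 replicates per assay per condition", call. = FALSE)
  }
  obs <- .activity_stats(ab, meta)
  conds <- colnames(obs$effect)
  pos_any <- obs$effect[, 1] > 0 | obs$effect[, 2] > 0
  n_pos <- sum(pos_any)

  set.seed(.substream(seed, "mstarr_perm"))
  pools <- list(methylated = list(), unmethylated = list())
  pairs <- split(seq_len(nrow(meta)), meta$pair)
  for (b in seq_len(n_perm)) {
    meta_p <- meta
    for (pr in pairs) {
      if (length(pr) == 2 && runif(1) < 0.5) {
        meta_p$assay[pr] <- rev(meta_p$assay[pr])
      }
    }
    st <- .activity_stats(ab, meta_p)
    ppos <- st$effect[, 1] > 0 | st$effect[, 2] > 0
    idx <- which(ppos)
    if (length(idx) > n_pos) idx <- sample(idx, n_pos)
    for (cond in conds) {
      pools[[cond]][[b]] <- st$p[idx, cond]
    }
  }
  res <- data.frame(window = seq_len(nrow(ab)),
                    effect_meth = obs$effect[, "methylated"],
                    effect_unmeth = obs$effect[, "unmethylated"],
                    p_meth = obs$p[, "methylated"],
                    p_unmeth = obs$p[, "unmethylated"],
                    q_meth = NA_real_, q_unmeth = NA_real_,
                    positive = pos_any)
  if (n_pos > 0) {
    for (cond in conds) {
      pool <- unlist(pools[[cond]])
      qq <- empirical_qvalues(obs$p[pos_any, cond], pool, n_perm)$qvalues
      col <- if (cond == "methylated") "q_meth" else "q_unmeth"
      res[[col]][pos_any] <- qq
    }
  }
  act_m <- res$positive & res$effect_meth > 0 & !is.na(res$q_meth) &
    res$q_meth < fdr
  act_u <- res$positive & res$effect_unmeth > 0 & !is.na(res$q_unmeth) &
    res$q_unmeth < fdr
  res$active <- act_m | act_u
  res$active_class <- ifelse(act_m & act_u, "active_both",
                       ifelse(act_m, "active_methylated_only",
                        ifelse(act_u, "active_unmethylated_only",
                               "inactive")))
  class(res) <- c("activity_call", "data.frame")
  res
}

#' Test active windows for methylation-dependent activity
#'
#' For windows in the active set, tests whether the RNA-vs-DNA effect
#' differs between the methylated and unmethylated conditions (interaction
#' contrast, pooled-variance test). The empirical null randomly reassigns
#' the condition label of each DNA-RNA replicate pair, restricted to the
#' active set.
#'
#' @param ab Normalized log2 abundance matrix.
#' @param meta Replicate metadata with `pair` indices.
#' @param active Indices (rows of `ab`) of the active windows.
#' @param n_perm Number of condition permutations.
#' @param seed Integer seed.
#' @param fdr Methylation-dependence threshold on q.
#' @return data.frame of class `"meth_dependence"`: per active window
#'   `window`, `interaction_effect` (unmethylated minus methylated
#'   activity), `interaction_p`, `interaction_q`, `meth_dependent`,
#'   `direction` ("more_active_unmethylated"/"more_active_methylated").
#' @export
test_methylation_dependence <- function(ab, meta, active, n_perm = 10,
                                        seed = 1L, fdr = 0.10) {
  if (length(active) == 0) {
    stop("the active set is empty: run test_activity first", call. = FALSE)
  }
  ab_a <- ab[active, , drop = FALSE]
  obs <- .activity_stats(ab_a, meta)
  set.seed(.substream(seed, "mstarr_perm") + 1L)
  # condition permutation operates on DNA-RNA pairs: each pair index groups
  # one DNA and one RNA replicate of the same condition
  pair_of <- meta$pair
  cond_of_pair <- tapply(meta$condition, pair_of, function(x) x[1])
  pool <- list()
  for (b in seq_len(n_perm)) {
    new_cond <- stats::setNames(sample(as.vector(cond_of_pair)),
                                names(cond_of_pair))
    meta_p <- meta
    meta_p$condition <- unname(new_cond[as.character(pair_of)])
    st <- .activity_stats(ab_a, meta_p)
    pool[[b]] <- st$interaction_p
  }
  qq <- empirical_qvalues(obs$interaction_p, unlist(pool), n_perm)$qvalues
  res <- data.frame(window = active,
                    interaction_effect = obs$interaction_effect,
                    interaction_p = obs$interaction_p,
                    interaction_q = qq,
                    meth_dependent = qq < fdr,
                    direction = ifelse(obs$interaction_effect > 0,
                                       "more_active_unmethylated",
                                       "more_active_methylated"))
  class(res) <- c("meth_dependence", "data.frame")
  res
}
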