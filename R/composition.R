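# The composition rule: ancestry effects predicted from meQTL effect sizes
# times parental allele-frequency divergence.

#' Population mean methylation of a biallelic meQTL
#'
#' Frequency-weighted mean of the two per-allele methylation probabilities:
#' `(1 - p_alt) * m_ref + p_alt * m_alt`.
#'
#' @param m_ref,m_alt Per-allele methylation probabilities in `[0, 1]`.
#' @param p_alt Alternate-allele frequency in `[0, 1]`.
#' @return Mean methylation level in `[0, 1]`.
#' @examples
#' # one allele never methylated, the other methylated half the time and
#' # segregating at 25%: mean methylation 12.5%
#' population_mean_methylation(0, 0.5, 0.25)
#' @export
population_mean_methylation <- function(m_ref, m_alt, p_alt) {
  .check_prob(m_ref, "m_ref")
  .check_prob(m_alt, "m_alt")
  .check_prob(p_alt, "p_alt")
  (1 - p_alt) * m_ref + p_alt * m_alt
}

#' Predict an ancestry effect from a meQTL effect and frequency divergence
#'
#' The predicted proportion-scale ancestry effect is the per-allele meQTL
#' effect times the parental allele-frequency difference:
#' `delta * (p_anubis - p_yellow)`. Positive values mean anubis ancestry is
#' more methylated.
#'
#' @param delta Per-allele meQTL effect on the proportion scale, in
#'   `[-1, 1]` (alternate minus reference allele).
#' @param p_yellow,p_anubis Alternate-allele frequencies in the two parental
#'   taxa.
#' @return Predicted proportion-scale ancestry effect.
#' @examples
#' predict_ancestry_effect(0.5, 0.25, 1.0)  # 0.375
#' @export
predict_ancestry_effect <- function(delta, p_yellow, p_anubis) {
  if (any(!is.finite(delta)) || any(abs(delta) > 1)) {
    stop("'delta' must be finite and in [-1, 1]", call. = FALSE)
  }
  .check_prob(p_yellow, "p_yellow")
  .check_prob(p_anubis, "p_anubis")
  delta * (p_anubis - p_yellow)
}

#' Build composition records
#'
#' Joins per-CpG meQTL effects with parental frequencies and observed
#' ancestry effects into one record per CpG, with the predicted effect and
#' the sign quadrant.
#'
#' @param delta Per-allele meQTL effects (proportion scale).
#' @param p_yellow,p_anubis Parental alternate-allele frequencies at the
#'   linked SNPs.
#' @param observed Observed proportion-scale ancestry effects (same
#'   per-allele convention as the prediction).
#' @param cpg_id Optional identifiers.
#' @param disrupted Optional logical stratification flag.
#' @return data.frame of class `"composition_records"` with columns
#'   `cpg_id`, `delta`, `p_yellow`, `p_anubis`, `predicted_effect`,
#'   `observed_effect`, `quadrant`, `disrupted`.
#' @export
composition_records <- function(delta, p_yellow, p_anubis, observed,
                                cpg_id = seq_along(delta),
                                disrupted = FALSE) {
  pred <- predict_ancestry_effect(delta, p_yellow, p_anubis)
  quadrant <- rep(NA_character_, length(pred))
  quadrant[pred >= 0 & observed >= 0] <- "I"
  quadrant[pred < 0 & observed >= 0] <- "II"
  quadrant[pred < 0 & observed < 0] <- "III"
  quadrant[pred >= 0 & observed < 0] <- "IV"
  out <- data.frame(cpg_id = cpg_id, delta = delta, p_yellow = p_yellow,
                    p_anubis = p_anubis, predicted_effect = pred,
                    observed_effect = observed, quadrant = quadrant,
                    disrupted = rep_len(disrupted, length(pred)))
  class(out) <- c("composition_records", "data.frame")
  out
}

#' Compare predicted and observed ancestry effects
#'
#' Rank correlation between predicted (meQTL effect x frequency divergence)
#' and observed ancestry effects, the fraction of sign-concordant records,
#' counts per sign quadrant, and the set of discordant-quadrant CpGs
#' (quadrants II and IV) exported as candidates for non-compositional
#' mechanisms.
#'
#' @param records A `composition_records` data.frame (finite predicted and
#'   observed effects; at least 3 records).
#' @return List of class `"composition_summary"`: `spearman_rho`,
#'   `pearson_r`, `frac_concordant`, `quadrant_counts`, `discordant`
#'   (records in quadrants II/IV), `degenerate` (TRUE when all ranks tie).
#' @export
compare_composition <- function(records) {
  r <- records[is.finite(records$predicted_effect) &
                 is.finite(records$observed_effect), ]
  if (nrow(r) < 3) stop("need at least 3 finite records", call. = FALSE)
  degen <- length(unique(r$predicted_effect)) == 1 ||
    length(unique(r$observed_effect)) == 1
  rho <- if (degen) NA_real_ else
    cor(r$predicted_effect, r$observed_effect, method = "spearman")
  pear <- if (degen) NA_real_ else
    cor(r$predicted_effect, r$observed_effect)
  nz <- r$predicted_effect != 0 & r$observed_effect != 0
  out <- list(
    spearman_rho = rho, pearson_r = pear,
    frac_concordant = mean(sign(r$predicted_effect[nz]) ==
                             sign(r$observed_effect[nz])),
    quadrant_counts = table(factor(r$quadrant, c("I", "II", "III", "IV"))),
    discordant = r[r$quadrant %in% c("II", "IV"), ],
    n = nrow(r), degenerate = degen)
  class(out) <- "composition_summary"
  out
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Predicted vs observed ancestry effects (composition rule)\n")
  cat(sprintf("  n = %d CpGs; Spearman rho = %.3f; Pearson r = %.3f\n",
              x$n, x$spearman_rho, x$pearson_r))
  cat(sprintf("  Sign concordance: %.1f%%\n", 100 * x$frac_concordant))
  cat("  Quadrant counts (predicted sign x observed sign):\n")
  print(x$quadrant_counts)
  if (x$degenerate) cat("  [degenerate: all ranks tied]\n")
  invisible(x)
}
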