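#' @keywords internal
#' @import stats
#' @importFrom utils read.table write.table modifyList
"_PACKAGE"

# Substream offsets: all randomness in the pipeline flows from one root seed;
# each stage draws from root_seed + offset (kept < 2^31).
.seed_offsets <- c(
  freqs = 101L, ancestry = 211L, genotypes = 307L, truth = 401L,
  methylation = 503L, reporter = 601L, scan_perm = 701L,
  species_perm = 809L, meqtl_perm = 907L, mstarr_perm = 1009L
)

.substream <- function(seed, stage) {
  off <- .seed_offsets[[stage]]
  as.integer((as.numeric(seed) + off) %% 2147483647)
}

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be finite and in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.check_counts <- function(meth, total) {
  k <- max(length(meth), length(total))
  meth <- rep_len(meth, k); total <- rep_len(total, k)
  if (any(meth < 0) || any(total < 0) || any(meth > total)) {
    stop("counts must satisfy 0 <= meth <= total", call. = FALSE)
  }
  invisible(NULL)
}

# Per-individual methylation ratios with zero-coverage individuals dropped.
.meth_ratio <- function(meth, total) {
  ok <- total > 0
  meth[ok] / total[ok]
}

.site_mean_methylation <- function(meth, total) {
  r <- .meth_ratio(meth, total)
  if (length(r) == 0) return(NA_real_)
  mean(r)
}
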