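# Plain-text writers and readers for the pipeline's standard formats.

#' Write genotypes to a VCF file
#'
#' Minimal VCFv4.2 with a GT field; unphased ("/") by default, phased ("|")
#' when haplotypes are supplied.
#'
#' @param genotypes A `genotypes` object.
#' @param loci data.frame with `chrom`, `pos` for the SNP loci (aligned to
#'   the genotype rows).
#' @param path Output path.
#' @param individuals Sample names.
#' @param phased Emit phased haplotypes?
#' @return Invisibly, the path.
#' @export
write_genotypes_vcf <- function(genotypes, loci, path,
                                individuals = paste0("ind",
                                  seq_len(ncol(genotypes$geno))),
                                phased = FALSE) {
  n <- ncol(genotypes$geno)
  m <- nrow(genotypes$geno)
  gt <- matrix("", m, n)
  if (phased) {
    gt[] <- paste(genotypes$hap1, genotypes$hap2, sep = "|")
  } else {
    g <- genotypes$geno
    gt[g == 0] <- "0/0"; gt[g == 1] <- "0/1"; gt[g == 2] <- "1/1"
    gt[is.na(g)] <- "./."
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individuals), collapse = "\t"))
  body <- vapply(seq_len(m), function(i) {
    paste(c(loci$chrom[i], loci$pos[i], paste0("snp", i), "A", "T", ".",
            "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write ancestry tracts to a BED-like file
#'
#' Columns chrom, start, end (0-based half-open), individual, haplotype,
#' dosage-contributing state.
#'
#' @param panel An `ancestry_panel`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ancestry_bed <- function(panel, path) {
  tr <- panel$tracts
  utils::write.table(
    data.frame(chrom = tr$chrom, start = format(tr$start, scientific = FALSE,
                                                trim = TRUE),
               end = format(tr$end, scientific = FALSE, trim = TRUE),
               individual = tr$individual, haplotype = tr$haplotype,
               state = tr$state),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write methylation counts to a long TSV
#'
#' Columns chrom, pos (1-based CpG cytosine, forward strand), individual,
#' meth, total.
#'
#' @param counts A `meth_counts` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_counts_tsv <- function(counts, path) {
  m <- nrow(counts$meth); n <- ncol(counts$meth)
  df <- data.frame(chrom = rep(counts$cpg_loci$chrom, n),
                   pos = rep(counts$cpg_loci$pos, n),
                   individual = rep(seq_len(n), each = m),
                   meth = as.vector(counts$meth),
                   total = as.vector(counts$total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long counts TSV back into matrices
#'
#' @param path TSV written by [write_counts_tsv()].
#' @return List with `meth`, `total` matrices (sites x individuals) and
#'   `cpg_loci`.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  key <- paste(df$chrom, df$pos)
  sites <- unique(key)
  inds <- sort(unique(df$individual))
  meth <- total <- matrix(0L, length(sites), length(inds))
  i <- match(key, sites); j <- match(df$individual, inds)
  meth[cbind(i, j)] <- df$meth
  total[cbind(i, j)] <- df$total
  first <- !duplicated(key)
  list(meth = meth, total = total,
       cpg_loci = data.frame(chrom = df$chrom[first], pos = df$pos[first]))
}

#' Write reporter counts to TSV
#'
#' @param reporter A `reporter_counts` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_reporter_tsv <- function(reporter, path) {
  utils::write.table(reporter$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth table to TSV
#'
#' @param truth A data.frame (e.g. from [simulate_truth()] or the reporter
#'   generator's `windows`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
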