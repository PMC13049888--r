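# Genomic-context annotation: CpG islands/shores, promoters, gene parts,
# enhancers; context enrichment and expression integration.

#' Detect CpG islands in a sequence
#'
#' Sliding-window scan (window `window` bp, step 1): a window qualifies when
#' its GC fraction exceeds `gc_min` and its observed/expected CpG ratio
#' (`n_CpG * L / (n_C * n_G)`) exceeds `oe_min`. A base is marked if any
#' qualifying window covers it; maximal marked runs longer than `min_len` bp
#' are reported as islands, with `shore` bp flanks on either side (clipped
#' at the sequence ends, never overlapping the island itself). Case and
#' trailing N padding are ignored.
#'
#' @param sequence Single character string (A/C/G/T/N).
#' @param window Scan window in bp.
#' @param min_len Minimum island length in bp (strict).
#' @param gc_min GC-content threshold (strict).
#' @param oe_min Observed/expected CpG threshold (strict).
#' @param shore Shore width in bp.
#' @return List with data.frames `islands` and `shores` (1-based inclusive
#'   `start`/`end`), empty when no island is found.
#' @export
find_cpg_islands <- function(sequence, window = 100, min_len = 200,
                             gc_min = 0.5, oe_min = 0.6, shore = 2000) {
  empty <- list(islands = data.frame(start = integer(0), end = integer(0)),
                shores = data.frame(start = integer(0), end = integer(0)))
  if (length(sequence) != 1 || is.na(sequence)) {
    stop("'sequence' must be a single string", call. = FALSE)
  }
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < window) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  isC <- as.integer(ch == "C")
  isG <- as.integer(ch == "G")
  isCpG <- as.integer(isC[-L] == 1L & isG[-1] == 1L)  # CpG starting at i
  cC <- c(0L, cumsum(isC))
  cG <- c(0L, cumsum(isG))
  cCpG <- c(0L, cumsum(isCpG))
  starts <- seq_len(L - window + 1L)
  nC <- cC[starts + window] - cC[starts]
  nG <- cG[starts + window] - cG[starts]
  # CpG dinucleotides fully inside the window start at i .. i + window - 2
  nCpG <- cCpG[starts + window - 1L] - cCpG[starts]
  gc <- (nC + nG) / window
  oe <- ifelse(nC > 0 & nG > 0, nCpG * window / (nC * nG), 0)
  qual <- gc > gc_min & oe > oe_min
  marked <- logical(L)
  if (any(qual)) {
    qs <- starts[qual]
    # mark all bases covered by qualifying windows
    d <- integer(L + 1L)
    d[qs] <- d[qs] + 1L
    d[qs + window] <- d[qs + window] - 1L
    marked <- cumsum(d[seq_len(L)]) > 0
  }
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths + 1L
  isl <- which(r$values & r$lengths > min_len)
  if (length(isl) == 0) return(empty)
  islands <- data.frame(start = starts_r[isl], end = ends[isl])
  shores <- do.call(rbind, lapply(seq_len(nrow(islands)), function(i) {
    left <- c(max(1L, islands$start[i] - shore), islands$start[i] - 1L)
    right <- c(islands$end[i] + 1L, min(L, islands$end[i] + shore))
    out <- NULL
    if (left[2] >= left[1]) out <- rbind(out, left)
    if (right[2] >= right[1]) out <- rbind(out, right)
    if (is.null(out)) return(NULL)
    data.frame(start = out[, 1], end = out[, 2])
  }))
  if (is.null(shores)) {
    shores <- data.frame(start = integer(0), end = integer(0))
  }
  rownames(shores) <- NULL
  list(islands = islands, shores = shores)
}

#' Assign genomic contexts to CpG sites
#'
#' Multi-label assignment: promoter (the 10 kb upstream of the 5'-most TSS,
#' strand-aware), exon, intron/UTR (inside the gene body but not in an
#' exon), enhancer, CpG island and CpG shore (island and shore are mutually
#' exclusive by construction of the shore intervals). Gene windows used for
#' CpG-gene pairing span TSS - `flank` to TES + `flank`, widened
#' symmetrically to at least `min_window` bp.
#'
#' @param cpgs data.frame with `chrom`, `pos` (1-based).
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`
#'   (+/-), `gene_id`, and optionally `exon_starts`/`exon_ends`
#'   (comma-separated strings).
#' @param enhancers Optional data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param islands Optional per-chromosome list of [find_cpg_islands()]
#'   results, named by chromosome.
#' @param flank Promoter length / gene-window flank in bp.
#' @param min_window Minimum total gene-window width in bp.
#' @return List of class `"genomic_context"`: `flags` (logical matrix CpG x
#'   context), `gene_of` (nearest gene-window assignment per CpG, NA when
#'   none).
#' @export
assign_context <- function(cpgs, genes, enhancers = NULL, islands = NULL,
                           flank = 10000, min_window = 50000) {
  chroms_g <- unique(as.character(genes$chrom))
  bad <- setdiff(unique(as.character(cpgs$chrom)), chroms_g)
  if (length(bad) && !is.null(genes) && nrow(genes)) {
    # CpGs on chromosomes absent from the gene model simply get no gene
    # contexts; a full mismatch is an input error
    if (length(bad) == length(unique(as.character(cpgs$chrom)))) {
      stop("chromosome names do not match the gene model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(cpgs)
  ctx <- c("promoter", "exon", "intron_utr", "enhancer", "cpg_island",
           "cpg_shore")
  flags <- matrix(FALSE, n, length(ctx), dimnames = list(NULL, ctx))
  gene_of <- rep(NA_character_, n)
  in_iv <- function(pos, chrom, iv_chrom, iv_start, iv_end) {
    hit <- rep(FALSE, length(pos))
    for (k in seq_along(iv_start)) {
      hit <- hit | (chrom == iv_chrom[k] & pos >= iv_start[k] &
                      pos <= iv_end[k])
    }
    hit
  }
  for (g in seq_len(nrow(genes))) {
    same <- as.character(cpgs$chrom) == as.character(genes$chrom[g])
    if (!any(same)) next
    pos <- cpgs$pos
    plus <- is.na(genes$strand[g]) || genes$strand[g] != "-"
    tss <- if (plus) genes$start[g] else genes$end[g]
    prom <- if (plus) c(tss - flank, tss - 1) else c(tss + 1, tss + flank)
    flags[, "promoter"] <- flags[, "promoter"] |
      (same & pos >= prom[1] & pos <= prom[2])
    body_hit <- same & pos >= genes$start[g] & pos <= genes$end[g]
    exon_hit <- rep(FALSE, n)
    if (!is.null(genes$exon_starts) && !is.na(genes$exon_starts[g]) &&
        nzchar(genes$exon_starts[g])) {
      es <- as.numeric(strsplit(genes$exon_starts[g], ",")[[1]])
      ee <- as.numeric(strsplit(genes$exon_ends[g], ",")[[1]])
      for (k in seq_along(es)) {
        exon_hit <- exon_hit | (same & pos >= es[k] & pos <= ee[k])
      }
    }
    flags[, "exon"] <- flags[, "exon"] | exon_hit
    flags[, "intron_utr"] <- flags[, "intron_utr"] | (body_hit & !exon_hit)
    w <- c(genes$start[g] - flank, genes$end[g] + flank)
    if (diff(w) + 1 < min_window) {
      pad <- ceiling((min_window - (diff(w) + 1)) / 2)
      w <- w + c(-pad, pad)
    }
    win_hit <- same & pos >= w[1] & pos <= w[2]
    gene_of[win_hit & is.na(gene_of)] <- as.character(genes$gene_id[g])
  }
  if (!is.null(enhancers) && nrow(enhancers)) {
    flags[, "enhancer"] <- in_iv(cpgs$pos, as.character(cpgs$chrom),
                                 as.character(enhancers$chrom),
                                 enhancers$start, enhancers$end)
  }
  if (!is.null(islands)) {
    for (chr in names(islands)) {
      same <- as.character(cpgs$chrom) == chr
      isl <- islands[[chr]]$islands
      sh <- islands[[chr]]$shores
      if (nrow(isl)) {
        flags[, "cpg_island"] <- flags[, "cpg_island"] |
          (same & in_iv(cpgs$pos, rep(chr, n), rep(chr, nrow(isl)),
                        isl$start, isl$end))
      }
      if (nrow(sh)) {
        flags[, "cpg_shore"] <- flags[, "cpg_shore"] |
          (same & in_iv(cpgs$pos, rep(chr, n), rep(chr, nrow(sh)),
                        sh$start, sh$end))
      }
    }
    flags[, "cpg_shore"] <- flags[, "cpg_shore"] & !flags[, "cpg_island"]
  }
  structure(list(flags = flags, gene_of = gene_of),
            class = "genomic_context")
}

#' Context enrichment of a foreground CpG set
#'
#' Per context, a 2x2 Fisher's exact test of foreground membership against
#' context membership over the background universe, with a Woolf (normal
#' approximation, Haldane-corrected) confidence interval on the log2 odds
#' ratio. Zero margins are flagged; the exact p is still reported.
#'
#' @param foreground Indices of foreground CpGs (subset of the background).
#' @param background Indices of the background universe.
#' @param flags Logical context matrix over the universe that `foreground`
#'   and `background` index into.
#' @return data.frame: per context `log2_or`, `ci_lo`, `ci_hi`, `p`,
#'   `n_fg_in`, `n_bg_in`, `degenerate`.
#' @export
context_enrichment <- function(foreground, background, flags) {
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background", call. = FALSE)
  }
  is_fg <- background %in% foreground
  out <- do.call(rbind, lapply(colnames(flags), function(ctx) {
    inc <- flags[background, ctx]
    a <- sum(is_fg & inc); b <- sum(is_fg & !inc)
    cc <- sum(!is_fg & inc); d <- sum(!is_fg & !inc)
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    woolf_se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (cc + 0.5) +
                       1 / (d + 0.5))
    lor <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5)))
    data.frame(context = ctx, log2_or = lor / log(2),
               ci_lo = (lor - 1.96 * woolf_se) / log(2),
               ci_hi = (lor + 1.96 * woolf_se) / log(2),
               p = ft$p.value, n_fg_in = a, n_bg_in = a + cc,
               degenerate = (a + cc == 0) || (b + d == 0) ||
                 (a + b == 0) || (cc + d == 0))
  }))
  rownames(out) <- NULL
  out
}

#' Integrate CpG ancestry effects with gene-expression ancestry effects
#'
#' Per context, a logistic regression of CpG significance status on the
#' absolute expression ancestry effect of the assigned gene; among jointly
#' significant CpG-gene pairs, a 2x2 Fisher's exact test of directional
#' concordance (sign of the methylation effect by sign of the expression
#' effect).
#'
#' @param cpg_sig Logical: CpG ancestry-associated?
#' @param cpg_effect Proportion-scale CpG ancestry effects.
#' @param gene_of Gene assignment per CpG (NA = unassigned).
#' @param expr_effects data.frame with `gene_id`, `effect`, `significant`.
#' @param flags Logical context matrix over the CpGs.
#' @param min_cpgs Minimum CpGs per context.
#' @return List: `logistic` (per context slope, se, p, n) and `concordance`
#'   (per context log2 OR, p, n). Contexts with fewer than `min_cpgs`
#'   assigned CpGs are skipped with a reason; all CpGs unassigned yields
#'   empty results with a warning.
#' @export
expression_integration <- function(cpg_sig, cpg_effect, gene_of,
                                   expr_effects, flags, min_cpgs = 20) {
  assigned <- !is.na(gene_of)
  if (!any(assigned)) {
    warning("no CpG is assigned to a gene")
    return(list(logistic = data.frame(), concordance = data.frame()))
  }
  idx <- which(assigned)
  ee <- expr_effects[match(gene_of[idx], expr_effects$gene_id), ]
  logistic <- list(); conc <- list()
  for (ctx in colnames(flags)) {
    in_ctx <- flags[idx, ctx] & !is.na(ee$effect)
    rows <- idx[in_ctx]
    sub <- which(in_ctx)
    if (length(rows) < min_cpgs) {
      logistic[[ctx]] <- data.frame(context = ctx, slope = NA_real_,
                                    se = NA_real_, p = NA_real_,
                                    n = length(rows),
                                    skipped = "too few CpGs")
      next
    }
    y <- as.integer(cpg_sig[rows])
    x <- abs(ee$effect[sub])
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    logistic[[ctx]] <- data.frame(context = ctx, slope = sm[2, 1],
                                  se = sm[2, 2], p = sm[2, 4],
                                  n = length(rows), skipped = "")
    joint <- cpg_sig[rows] & ee$significant[sub]
    if (sum(joint, na.rm = TRUE) >= 4) {
      ms <- cpg_effect[rows][joint] > 0
      es <- ee$effect[sub][joint] > 0
      tab <- table(factor(ms, c(FALSE, TRUE)), factor(es, c(FALSE, TRUE)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ft <- stats::fisher.test(tab)
        conc[[ctx]] <- data.frame(context = ctx,
                                  log2_or = log2(ft$estimate[[1]]),
                                  p = ft$p.value, n = sum(joint))
      }
    }
  }
  list(logistic = do.call(rbind, logistic),
       concordance = if (length(conc)) do.call(rbind, conc)
                     else data.frame())
}
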