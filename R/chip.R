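#' Window parameters for ChIP coverage analysis
#'
#' @param bin_width bin width in base pairs (default 100).
#' @param read_extension length each read is extended to from its 5' end in
#'   its strand direction (default 300).
#' @param flank_upstream upstream flank added to each gene body, strand-aware
#'   (default 2000).
#' @param fdr_alpha Benjamini-Hochberg FDR level for differential windows.
#' @return Object of class `window_params`.
#' @export
window_params <- function(bin_width = 100L, read_extension = 300L,
                          flank_upstream = 2000L, fdr_alpha = 0.05) {
  stopifnot(bin_width > 0, read_extension > 0, flank_upstream > 0,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(bin_width = as.integer(bin_width),
                 read_extension = as.integer(read_extension),
                 flank_upstream = as.integer(flank_upstream),
                 fdr_alpha = fdr_alpha),
            class = "window_params")
}

new_coverage_bins <- function(bins, counts, bin_width) {
  stopifnot(nrow(bins) == nrow(counts))
  structure(list(bins = bins, counts = counts, bin_width = bin_width),
            class = "coverage_bins")
}

#' @export
print.coverage_bins <- function(x, ...) {
  cat(sprintf("Coverage bins: %d bins of %d bp on %d chromosome(s), %d sample(s)\n",
              nrow(x$bins), x$bin_width, length(unique(x$bins$chrom)),
              ncol(x$counts)))
  invisible(x)
}

#' Bin extended-read coverage into fixed-width windows
#'
#' Each read is extended to `read_extension` bases from its 5' end in its
#' strand direction (clipped to the chromosome), and increments every
#' half-open bin `[k*w, (k+1)*w)` it overlaps. Identical `(chrom, 5' end,
#' strand)` placements are collapsed as presumed PCR duplicates unless
#' `dedup = FALSE`.
#'
#' @param reads per-sample read placements: a named list of data.frames with
#'   columns `chrom`, `start`, `end` (0-based half-open) and `strand`.
#' @param genome_sizes named numeric, chromosome lengths in bp.
#' @param params a [window_params()].
#' @param dedup collapse duplicate placements.
#' @return A `coverage_bins` object; reads extending past a chromosome end
#'   are clipped with a count recorded in `attr(, "clipped")`.
#' @export
bin_coverage <- function(reads, genome_sizes, params = window_params(),
                         dedup = TRUE) {
  stopifnot(is.list(reads), !is.null(names(genome_sizes)))
  w <- params$bin_width
  bins <- do.call(rbind, lapply(names(genome_sizes), function(ch) {
    nb <- ceiling(genome_sizes[[ch]] / w)
    if (nb == 0) return(NULL)
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * w,
               end = pmin(seq_len(nb) * w, genome_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  counts <- matrix(0, nrow = if (is.null(bins)) 0 else nrow(bins),
                   ncol = length(reads),
                   dimnames = list(NULL, names(reads)))
  clipped <- stats::setNames(integer(length(reads)), names(reads))
  for (s in names(reads)) {
    rd <- reads[[s]]
    if (is.null(rd) || nrow(rd) == 0) next
    stopifnot(all(c("chrom", "start", "end", "strand") %in% names(rd)))
    five <- ifelse(rd$strand == "-", rd$end, rd$start)
    if (dedup) {
      keep <- !duplicated(paste(rd$chrom, five, rd$strand))
      rd <- rd[keep, , drop = FALSE]; five <- five[keep]
    }
    ext_start <- ifelse(rd$strand == "-", five - params$read_extension, five)
    ext_end <- ext_start + params$read_extension
    lim <- genome_sizes[rd$chrom]
    clip <- ext_start < 0 | ext_end > lim
    clipped[s] <- sum(clip)
    ext_start <- pmax(0, ext_start)
    ext_end <- pmin(lim, ext_end)
    ok <- ext_end > ext_start & rd$chrom %in% names(genome_sizes)
    for (ch in unique(rd$chrom[ok])) {
      i <- ok & rd$chrom == ch
      brow <- which(bins$chrom == ch)
      ir_read <- IRanges::IRanges(start = ext_start[i] + 1L, end = ext_end[i])
      ir_bin <- IRanges::IRanges(start = bins$start[brow] + 1L,
                                 end = bins$end[brow])
      counts[brow, s] <- counts[brow, s] +
        IRanges::countOverlaps(ir_bin, ir_read)
    }
  }
  out <- new_coverage_bins(bins, counts, w)
  attr(out, "clipped") <- clipped
  out
}

#' Differential coverage of binned ChIP signal between two groups
#'
#' Bin counts are scaled by TMM factors computed on the bin matrix, then each
#' bin with any signal is compared between the groups by Welch's test on
#' `log2(scaled + 0.5)` when both groups have replicates; p-values are
#' Benjamini-Hochberg corrected over all tested bins. With single-sample
#' groups only descriptive fold changes are returned (flagged).
#'
#' @param bins a `coverage_bins` object.
#' @param group1,group2 character vectors of sample ids.
#' @param params a [window_params()] (uses `fdr_alpha`).
#' @return Object of class `window_diff`: data.frame per tested bin with
#'   group means (scaled), `logFC` (group1 over group2), `p`, `q` and
#'   `significant`; untested (all-zero) bins are omitted.
#'   `attr(, "descriptive")` marks the no-replicate mode.
#' @export
differential_windows <- function(bins, group1, group2,
                                 params = window_params()) {
  stopifnot(inherits(bins, "coverage_bins"))
  cnt <- bins$counts[, c(group1, group2), drop = FALSE]
  if (all(cnt == 0)) {
    warning("all-zero coverage matrix; nothing to test", call. = FALSE)
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean1 = numeric(0),
                      mean2 = numeric(0), logFC = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
    class(out) <- c("window_diff", "data.frame")
    return(out)
  }
  rownames(cnt) <- seq_len(nrow(cnt))
  factors <- tmm_factors(cnt)
  scaled <- cpm(cnt, factors)
  test <- rowSums(cnt) > 0
  sc <- scaled[test, , drop = FALSE]
  m1 <- rowMeans(sc[, group1, drop = FALSE])
  m2 <- rowMeans(sc[, group2, drop = FALSE])
  descriptive <- length(group1) < 2L || length(group2) < 2L
  if (!descriptive) {
    lg <- log2(sc + 0.5)
    ws <- row_welch(lg, group1, group2)
    p <- ws$p
    q <- benjamini_hochberg(p)
    sig <- q < params$fdr_alpha
  } else {
    p <- q <- rep(NA_real_, nrow(sc)); sig <- rep(NA, nrow(sc))
  }
  out <- data.frame(bins$bins[test, , drop = FALSE], mean1 = m1, mean2 = m2,
                    logFC = log2((m1 + 0.5) / (m2 + 0.5)), p = p, q = q,
                    significant = sig, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "descriptive") <- descriptive
  class(out) <- c("window_diff", "data.frame")
  out
}

## vectorized Welch over matrix rows
row_welch <- function(m, g1, g2) {
  x <- m[, g1, drop = FALSE]; y <- m[, g2, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  dm <- m1 - m2
  zero <- se2 == 0
  t[zero] <- ifelse(dm[zero] == 0, 0, sign(dm[zero]) * Inf)
  p[zero] <- ifelse(dm[zero] == 0, 1, 0)
  list(statistic = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order (step-up: sort ascending,
#'   `q_i = min over j >= i of p_j * n / j`, clipped at 1).
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Gene-level H3K27me3 accumulation scores
#'
#' For each gene, sums the bin counts over the gene body plus a strand-aware
#' upstream flank (`[max(0, start - flank), end)` on the plus strand,
#' `[start, end + flank)` on the minus strand, clipped to the chromosome),
#' weighting partially overlapped bins by their overlap fraction, and
#' normalizes by sample depth to per-million units.
#'
#' @param bins a `coverage_bins` object.
#' @param annotation gene intervals with `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param params a [window_params()] (uses `flank_upstream`).
#' @param design optional design table; when given, per-condition mean
#'   accumulations are attached.
#' @return Object of class `gene_chip_scores`: list with `scores`
#'   (genes x samples matrix, per-million), `condition_means` (or NULL) and
#'   `skipped` (genes on unknown chromosomes).
#' @export
gene_accumulation <- function(bins, annotation, params = window_params(),
                              design = NULL) {
  stopifnot(inherits(bins, "coverage_bins"))
  ann <- annotation
  known <- ann$chrom %in% unique(bins$bins$chrom)
  skipped <- ann$gene[!known]
  ann <- ann[known, , drop = FALSE]
  depth <- colSums(bins$counts)
  depth[depth == 0] <- 1
  scores <- matrix(0, nrow(ann), ncol(bins$counts),
                   dimnames = list(ann$gene, colnames(bins$counts)))
  for (ch in unique(ann$chrom)) {
    gi <- which(ann$chrom == ch)
    brow <- which(bins$bins$chrom == ch)
    chrom_end <- max(bins$bins$end[brow])
    ws <- ifelse(ann$strand[gi] == "-", ann$start[gi],
                 pmax(0, ann$start[gi] - params$flank_upstream))
    we <- ifelse(ann$strand[gi] == "-",
                 pmin(chrom_end, ann$end[gi] + params$flank_upstream),
                 ann$end[gi])
    ir_win <- IRanges::IRanges(start = ws + 1L, end = we)
    ir_bin <- IRanges::IRanges(start = bins$bins$start[brow] + 1L,
                               end = bins$bins$end[brow])
    hit <- IRanges::findOverlaps(ir_win, ir_bin)
    if (length(hit) == 0) next
    qh <- S4Vectors_queryHits(hit); sh <- S4Vectors_subjectHits(hit)
    ov <- IRanges::width(IRanges::pintersect(ir_win[qh], ir_bin[sh]))
    wfrac <- ov / IRanges::width(ir_bin[sh])
    contrib <- bins$counts[brow[sh], , drop = FALSE] * wfrac
    agg <- rowsum(contrib, group = qh)
    rows <- as.integer(rownames(agg))
    scores[gi[rows], ] <- scores[gi[rows], , drop = FALSE] + agg
  }
  scores <- t(t(scores) / depth) * 1e6
  condition_means <- NULL
  if (!is.null(design)) {
    design <- design[design$sample %in% colnames(scores), , drop = FALSE]
    conds <- unique(design$condition)
    condition_means <- vapply(conds, function(cc)
      rowMeans(scores[, design$sample[design$condition == cc], drop = FALSE]),
      numeric(nrow(scores)))
    condition_means <- matrix(condition_means, nrow = nrow(scores),
                              dimnames = list(rownames(scores), conds))
  }
  structure(list(scores = scores, condition_means = condition_means,
                 skipped = skipped),
            class = "gene_chip_scores")
}

#' @export
print.gene_chip_scores <- function(x, ...) {
  cat(sprintf("Gene H3K27me3 accumulation: %d genes x %d samples (per-million)\n",
              nrow(x$scores), ncol(x$scores)))
  if (length(x$skipped))
    cat("  skipped (unknown chromosome):", length(x$skipped), "\n")
  invisible(x)
}

#' Integrate expression ratios with H3K27me3 accumulation
#'
#' Per shared gene, pairs the expression ratio for a condition comparison
#' (e.g. treated over untreated) with the accumulation difference of the
#' same comparison, tests the per-gene accumulation difference (Welch across
#' replicate accumulations, Benjamini-Hochberg over genes), classifies genes
#' as `inactivated_with_H3K27me3` when the expression ratio falls to at most
#' `1 - decrease_threshold` of baseline and the accumulation gain is
#' significant, and reports the Spearman rank correlation between the
#' expression ratio and the accumulation delta.
#'
#' @param ratios a `ratio_table`.
#' @param chip a `gene_chip_scores`.
#' @param design design table mapping samples to conditions.
#' @param comparison length-2 character: numerator and denominator
#'   conditions (default treated over untreated).
#' @param decrease_threshold expression decrease defining inactivation
#'   (default 2/3, i.e. ratio <= 1/3).
#' @param fdr_alpha FDR level for the per-gene accumulation test.
#' @return Object of class `chip_integration`: data.frame per gene with
#'   `expr_ratio`, `chip_delta`, `p`, `q`, `classified`; the Spearman
#'   correlation in `attr(, "spearman")`.
#' @export
integrate_expression_chip <- function(ratios, chip, design,
                                      comparison = c("Dplus", "Dminus"),
                                      decrease_threshold = 2 / 3,
                                      fdr_alpha = 0.05) {
  stopifnot(inherits(ratios, "ratio_table"), inherits(chip, "gene_chip_scores"),
            length(comparison) == 2L)
  genes <- intersect(ratios$gene, rownames(chip$scores))
  if (length(genes) == 0) {
    warning("no genes shared between expression and ChIP inputs", call. = FALSE)
    out <- data.frame(gene = character(0), expr_ratio = numeric(0),
                      chip_delta = numeric(0), p = numeric(0), q = numeric(0),
                      classified = logical(0))
    attr(out, "spearman") <- NA_real_
    class(out) <- c("chip_integration", "data.frame")
    return(out)
  }
  idx <- match(genes, ratios$gene)
  num <- ratios[[comparison[1]]][idx]
  den <- ratios[[comparison[2]]][idx]
  expr_ratio <- num / den
  s1 <- design$sample[design$condition == comparison[1]]
  s2 <- design$sample[design$condition == comparison[2]]
  s1 <- intersect(s1, colnames(chip$scores))
  s2 <- intersect(s2, colnames(chip$scores))
  acc <- chip$scores[genes, , drop = FALSE]
  delta <- rowMeans(acc[, s1, drop = FALSE]) - rowMeans(acc[, s2, drop = FALSE])
  if (length(s1) >= 2L && length(s2) >= 2L) {
    ws <- row_welch(acc, s1, s2)
    p <- ws$p
    q <- benjamini_hochberg(p)
  } else {
    p <- q <- rep(NA_real_, length(genes))
  }
  classified <- !is.na(expr_ratio) & expr_ratio <= 1 - decrease_threshold &
    !is.na(q) & q < fdr_alpha & delta > 0
  out <- data.frame(gene = genes, expr_ratio = expr_ratio, chip_delta = delta,
                    p = p, q = q, classified = classified,
                    stringsAsFactors = FALSE)
  ok <- is.finite(out$expr_ratio) & is.finite(out$chip_delta)
  attr(out, "spearman") <- if (sum(ok) >= 3 &&
                               stats::sd(out$expr_ratio[ok]) > 0 &&
                               stats::sd(out$chip_delta[ok]) > 0)
    stats::cor(out$expr_ratio[ok], out$chip_delta[ok], method = "spearman")
    else NA_real_
  attr(out, "comparison") <- comparison
  class(out) <- c("chip_integration", "data.frame")
  out
}

#' @export
print.chip_integration <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("Expression-H3K27me3 integration (%s/%s): %d genes\n",
              cmp[1], cmp[2], nrow(x)))
  cat(sprintf("  classified inactivated_with_H3K27me3: %d\n", sum(x$classified)))
  cat(sprintf("  Spearman(expression ratio, accumulation delta) = %.3f\n",
              attr(x, "spearman")))
  invisible(x)
}
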