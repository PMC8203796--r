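#' Chromosome-level silencing summary
#'
#' For each chromosome, collects the per-gene log-transformed expression
#' ratios of the trisomic lines (`Dminus`, `Dplus`, `Dremov`) relative to the
#' control, tests for an across-line difference with the Kruskal-Wallis test
#' (genes as observations, lines as groups), and Bonferroni-multiplies the
#' p-values by the number of chromosomes tested. Linear-scale mean ratios
#' per line are reported alongside.
#'
#' @param ratios a [ratio_table()].
#' @param annotation data.frame with `gene` and `chrom` columns covering all
#'   ratio-table genes.
#' @param log_base base of the log transform (default 2).
#' @param dosage_chromosome label flagged in the output (optional).
#' @return Object of class `chromosome_summary`: data.frame with one row per
#'   chromosome (`chrom`, `n_genes`, `n_dropped`, per-line linear means and
#'   log-ratio means/SDs/quartiles, `kw_stat`, `p_value`, `p_bonferroni`,
#'   `dosage`), carrying the per-chromosome log-ratio lists in
#'   `attr(, "logratios")`.
#' @export
chromosome_ratio_summary <- function(ratios, annotation, log_base = 2,
                                     dosage_chromosome = NULL) {
  stopifnot(inherits(ratios, "ratio_table"))
  lines <- intersect(c("Dminus", "Dplus", "Dremov"), names(ratios))
  if (length(lines) < 2L) stop("ratio table lacks trisomic lines", call. = FALSE)
  miss <- setdiff(ratios$gene, annotation$gene)
  if (length(miss))
    stop("annotation missing for genes: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  chrom <- annotation$chrom[match(ratios$gene, annotation$gene)]
  chroms <- unique(chrom)

  logratios <- list()
  rows <- lapply(chroms, function(ch) {
    sub <- ratios[chrom == ch, , drop = FALSE]
    defined <- stats::complete.cases(sub[, lines, drop = FALSE]) &
      apply(sub[, lines, drop = FALSE] > 0, 1, all)
    n_drop <- sum(!defined)
    sub <- sub[defined, , drop = FALSE]
    lr <- lapply(lines, function(l) log(sub[[l]], base = log_base))
    names(lr) <- lines
    logratios[[ch]] <<- lr
    kw_stat <- NA_real_; p <- NA_real_
    if (nrow(sub) >= 2L) {
      kw <- stats::kruskal.test(unlist(lr, use.names = FALSE),
                                factor(rep(lines, each = nrow(sub))))
      kw_stat <- unname(kw$statistic); p <- kw$p.value
    }
    qs <- vapply(lr, function(v)
      if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3),
      numeric(3))
    stats_row <- c(
      stats::setNames(vapply(lines, function(l) mean(sub[[l]]), numeric(1)),
                      paste0("mean_", lines)),
      stats::setNames(vapply(lr, mean, numeric(1)), paste0("logmean_", lines)),
      stats::setNames(vapply(lr, stats::sd, numeric(1)), paste0("logsd_", lines)),
      stats::setNames(as.vector(qs),
                      paste0(rep(c("q25_", "q50_", "q75_"), length(lines)),
                             rep(lines, each = 3))))
    data.frame(chrom = ch, n_genes = nrow(sub), n_dropped = n_drop,
               t(stats_row), kw_stat = kw_stat, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * length(chroms), 1)
  out$dosage <- if (is.null(dosage_chromosome)) FALSE else
    out$chrom == dosage_chromosome
  attr(out, "logratios") <- logratios
  attr(out, "log_base") <- log_base
  class(out) <- c("chromosome_summary", "data.frame")
  out
}

#' @export
print.chromosome_summary <- function(x, ...) {
  cat("Chromosome-level silencing summary (", nrow(x), " chromosomes)\n", sep = "")
  cols <- intersect(c("chrom", "n_genes", "mean_Dminus", "mean_Dplus",
                      "mean_Dremov", "kw_stat", "p_bonferroni", "dosage"),
                    names(x))
  print.data.frame(x[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.chromosome_summary <- function(x, ...) {
  lr <- attr(x, "logratios")
  lines <- names(lr[[1]])
  vals <- unlist(lapply(lr, function(l) unlist(l)), use.names = FALSE)
  grp <- unlist(lapply(names(lr), function(ch)
    rep(paste(ch, lines, sep = ":"), lengths(lr[[ch]]))), use.names = FALSE)
  graphics::boxplot(vals ~ factor(grp, levels = unique(grp)), las = 2,
                    ylab = sprintf("log%g expression ratio", attr(x, "log_base")),
                    xlab = "", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Hierarchical clustering of dosage-chromosome genes
#'
#' Agglomerative clustering of genes over their log-ratio profiles across the
#' trisomic lines, mirroring the heatmap/cluster view of chromosome-wide
#' transcriptional dynamics. Genes are sorted by id before clustering so the
#' result is invariant to input order; a constant matrix yields a valid
#' degenerate tree with zero merge heights.
#'
#' @param ratios a `ratio_table` already restricted to the genes of interest
#'   (typically the dosage chromosome).
#' @param linkage_method,distance_metric passed to [stats::hclust()] /
#'   [stats::dist()] (defaults: average linkage, euclidean distance on log2
#'   ratios).
#' @param log_base base for the log transform of the ratio profiles.
#' @return Object of class `gene_cluster`: list with `order` (leaf ids left
#'   to right), `merge`, `height`, `labels`, the profile `matrix`, and the
#'   underlying `hclust` object.
#' @export
cluster_chr21_genes <- function(ratios, linkage_method = "average",
                                distance_metric = "euclidean", log_base = 2) {
  stopifnot(inherits(ratios, "ratio_table"))
  lines <- intersect(c("Dminus", "Dplus", "Dremov"), names(ratios))
  if (nrow(ratios) < 2L) stop("need at least two genes to cluster", call. = FALSE)
  ratios <- ratios[order(ratios$gene), , drop = FALSE]
  m <- as.matrix(ratios[, lines, drop = FALSE])
  rownames(m) <- ratios$gene
  keep <- stats::complete.cases(m) & apply(m > 0, 1, all)
  m <- log(m[keep, , drop = FALSE], base = log_base)
  if (nrow(m) < 2L) stop("fewer than two genes with defined ratios", call. = FALSE)
  hc <- stats::hclust(stats::dist(m, method = distance_metric),
                      method = linkage_method)
  structure(list(order = rownames(m)[hc$order], merge = hc$merge,
                 height = hc$height, labels = rownames(m), matrix = m,
                 hclust = hc),
            class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat("Gene cluster over", length(x$labels), "genes;",
      length(x$height), "merges, max height", format(max(x$height), digits = 4), "\n")
  invisible(x)
}
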