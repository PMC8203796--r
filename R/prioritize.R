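#' Thresholds for candidate-gene prioritization
#'
#' @param fold_up minimum trisomic/control ratio for the dosage-response
#'   stage (default 1.5).
#' @param alpha two-sided Welch-test level for the silencing stage.
#' @param rank_primary,rank_secondary component-score rank tiers (top 10 and
#'   top 50 of all scored dosage-chromosome genes).
#' @param reversion_min minimum reversion fraction
#'   `(Dremov - Dplus) / (Dminus - Dplus)` for a gene to count as reverted.
#' @return Object of class `prioritization_thresholds`.
#' @export
prioritization_thresholds <- function(fold_up = 1.5, alpha = 0.05,
                                      rank_primary = 10L, rank_secondary = 50L,
                                      reversion_min = 0.1) {
  stopifnot(fold_up > 0, alpha > 0, alpha < 1,
            rank_primary <= rank_secondary,
            reversion_min >= 0, reversion_min <= 1)
  structure(list(fold_up = fold_up, alpha = alpha,
                 rank_primary = as.integer(rank_primary),
                 rank_secondary = as.integer(rank_secondary),
                 reversion_min = reversion_min),
            class = "prioritization_thresholds")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' and a two-sided p-value. Unlike [stats::t.test()], degenerate inputs are
#' defined: when both groups are constant the test returns `t = 0, p = 1`
#' for equal means and a decisive `|t| = Inf, p = 0` otherwise.
#'
#' @param x,y numeric vectors, each with at least two values.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two replicates", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("non-finite values", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    return(list(statistic = t, df = length(x) + length(y) - 2,
                p.value = if (dm == 0) 1 else 0))
  }
  se2 <- vx / length(x) + vy / length(y)
  t <- dm / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                 vy^2 / (length(y)^2 * (length(y) - 1)))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

## relative tolerance for >=-threshold comparisons: absorbs float noise at
## exact ties (e.g. a noiseless ratio of 1.5 computed as 1.5 - 2e-16) without
## moving any data-scale decision
THRESHOLD_EPS <- 1e-9

reversion_fraction <- function(dminus, dplus, dremov) {
  denom <- dminus - dplus
  out <- (dremov - dplus) / denom
  out[!is.finite(out) | denom <= 0] <- NA_real_
  out
}

#' Filter cascade for silencing-responsive, reverting genes
#'
#' Applies the staged gene filters on the dosage chromosome:
#' S1 genes with positive read counts in the trisomic lines; S2 those with
#' trisomic/control ratio >= `fold_up`; S3 those whose mean normalized
#' expression drops under treatment; S4 those where the drop is significant
#' by Welch's test on per-sample normalized abundances (`p < alpha`);
#' S5 those whose expression reverts after withdrawal
#' (reversion fraction >= `reversion_min`). Stages are nested by
#' construction. Genes whose reversion fraction is undefined
#' (`Dminus <= Dplus` on condition means) fail S5 with a recorded reason.
#'
#' @param counts genes x samples raw count matrix.
#' @param ratios the matching [ratio_table()].
#' @param design sample-to-condition design.
#' @param annotation data.frame with `gene` and `chrom`.
#' @param dosage_chromosome chromosome restricted to.
#' @param thresholds a [prioritization_thresholds()].
#' @param include_control passed to [positive_count_filter()].
#' @return Object of class `cascade_result`: list with `stages`
#'   (`S1`..`S5` character vectors), `stats` (per-S1-gene data.frame of
#'   ratios, Welch t/p, reversion fraction and stage flags) and `thresholds`.
#' @export
filter_cascade <- function(counts, ratios, design, annotation,
                           dosage_chromosome,
                           thresholds = prioritization_thresholds(),
                           include_control = FALSE) {
  counts <- as_count_matrix(counts)
  design <- check_design(counts, design,
                         need = c("cDi21", "Dminus", "Dplus", "Dremov"))
  for (cc in c("Dminus", "Dplus"))
    if (sum(design$condition == cc) < 2L)
      stop("Welch stage needs >= 2 replicates in ", cc, call. = FALSE)
  x <- attr(ratios, "cpm")
  if (is.null(x)) stop("ratio table lacks per-sample normalized values; ",
                       "build it with ratio_table()", call. = FALSE)
  th <- thresholds

  chrom <- annotation$chrom[match(rownames(counts), annotation$gene)]
  dosage_genes <- rownames(counts)[!is.na(chrom) & chrom == dosage_chromosome]
  S1 <- intersect(positive_count_filter(counts, design, include_control),
                  dosage_genes)

  idx <- match(S1, ratios$gene)
  dminus <- ratios$Dminus[idx]; dplus <- ratios$Dplus[idx]
  dremov <- ratios$Dremov[idx]
  in2 <- !is.na(dminus) & dminus >= th$fold_up * (1 - THRESHOLD_EPS)
  in3 <- in2 & !is.na(dplus) & dplus < dminus

  sm <- design$sample[design$condition == "Dminus"]
  sp <- design$sample[design$condition == "Dplus"]
  tt <- lapply(S1, function(g) welch_t_test(x[g, sm], x[g, sp]))
  t_stat <- vapply(tt, `[[`, numeric(1), "statistic")
  p_val <- vapply(tt, `[[`, numeric(1), "p.value")
  in4 <- in3 & p_val < th$alpha

  rf <- reversion_fraction(dminus, dplus, dremov)
  in5 <- in4 & !is.na(rf) & rf >= th$reversion_min * (1 - THRESHOLD_EPS)

  stats_df <- data.frame(gene = S1, Dminus = dminus, Dplus = dplus,
                         Dremov = dremov, t = t_stat, p = p_val,
                         reversion = rf, S2 = in2, S3 = in3, S4 = in4,
                         S5 = in5, stringsAsFactors = FALSE)
  structure(list(stages = list(S1 = S1, S2 = S1[in2], S3 = S1[in3],
                               S4 = S1[in4], S5 = S1[in5]),
                 stats = stats_df, thresholds = th,
                 dosage_chromosome = dosage_chromosome),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  n <- lengths(x$stages)
  cat("Filter cascade on", x$dosage_chromosome, "\n")
  cat(sprintf("  S1 positive counts: %d\n  S2 fold >= %.3g: %d\n", n[1],
              x$thresholds$fold_up, n[2]))
  cat(sprintf("  S3 decreased under treatment: %d\n  S4 Welch p < %.3g: %d\n",
              n[3], x$thresholds$alpha, n[4]))
  cat(sprintf("  S5 reverted (fraction >= %.3g): %d\n",
              x$thresholds$reversion_min, n[5]))
  invisible(x)
}

#' First-principal-component gene scores
#'
#' Samples are observations and genes variables; each gene is centered across
#' samples (no variance scaling) and the first principal axis is taken from
#' the singular-value decomposition. The per-gene score is the component-1
#' loading; loadings have unit euclidean norm; the sign is fixed so the sum
#' of loadings over genes with trisomic ratio > 1 is non-negative; genes
#' constant across samples get loading exactly 0 (with the remaining
#' loadings renormalized). Ranks are by absolute loading, descending, ties
#' broken by gene id.
#'
#' @param expr samples x genes numeric matrix (typically per-sample log2
#'   ratios to the control mean; see [prioritize()]).
#' @param dminus_ratio named numeric of trisomic/control ratios used for the
#'   sign convention (optional; default fixes the sign by the total loading
#'   sum).
#' @return List with `scores` (data.frame: gene, loading, abs_loading,
#'   rank), `sample_scores` (samples x 2 coordinate matrix) and `sdev`.
#' @export
pca_gene_scores <- function(expr, dminus_ratio = NULL) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("PCA needs at least two samples", call. = FALSE)
  if (ncol(expr) < 2L) stop("PCA needs at least two genes", call. = FALSE)
  if (is.null(colnames(expr))) stop("gene column names required", call. = FALSE)
  ctr <- scale(expr, center = TRUE, scale = FALSE)
  const <- apply(ctr, 2, function(v) all(v == 0))
  loading <- stats::setNames(rep(0, ncol(expr)), colnames(expr))
  sample_scores <- matrix(0, nrow(expr), 2,
                          dimnames = list(rownames(expr), c("PC1", "PC2")))
  sdev <- c(0, 0)
  if (sum(!const) >= 1L) {
    sv <- svd(ctr[, !const, drop = FALSE])
    v1 <- sv$v[, 1]
    loading[!const] <- v1 / sqrt(sum(v1^2))
    sgn_genes <- if (!is.null(dminus_ratio)) {
      g <- names(dminus_ratio)[!is.na(dminus_ratio) & dminus_ratio > 1]
      intersect(g, colnames(expr))
    } else colnames(expr)
    s <- sum(loading[sgn_genes])
    if (s < 0) { loading <- -loading; sv$u[, 1] <- -sv$u[, 1] }
    k <- min(2, ncol(sv$u))
    sample_scores[, seq_len(k)] <-
      sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    sdev <- sv$d[seq_len(min(2, length(sv$d)))] / sqrt(max(1, nrow(expr) - 1))
  }
  ord <- order(-abs(loading), names(loading))
  rank <- integer(length(loading)); rank[ord] <- seq_along(loading)
  scores <- data.frame(gene = names(loading), loading = unname(loading),
                       abs_loading = abs(unname(loading)),
                       rank = rank, stringsAsFactors = FALSE)
  list(scores = scores, sample_scores = sample_scores, sdev = sdev)
}

#' Select candidate genes from scores, region and expression rules
#'
#' The shortlist is every scored gene whose interval overlaps the critical
#' region (any base-pair overlap, half-open arithmetic) and whose
#' chromosome-wide component-score rank is within `rank_secondary`. Two
#' exclusion rules are then applied on the ratio table: `low_Dminus` when the
#' trisomic/control ratio falls below `fold_up`, and `no_reversion` when the
#' reversion fraction falls below `reversion_min` (or is undefined). The
#' final candidates are the shortlist minus the exclusions; each decision is
#' recorded with its numeric basis.
#'
#' @param scores data.frame with columns `gene`, `loading`, `abs_loading`,
#'   `rank` (as from [pca_gene_scores()], or the packaged fixture where the
#'   printed ranks stand in).
#' @param ratios a `ratio_table` covering the scored genes.
#' @param annotation gene intervals (`gene`, `chrom`, `start`, `end`);
#'   optional when `region_genes` is given directly.
#' @param region length-2 numeric half-open interval on
#'   `dosage_chromosome`; used with `annotation`.
#' @param region_genes character vector naming the region members directly
#'   (fixture mode).
#' @param dosage_chromosome chromosome holding the region.
#' @param thresholds a [prioritization_thresholds()].
#' @return Object of class `candidate_report`: list with `shortlist`
#'   (data.frame with rank tier and ratio evidence), `exclusions`
#'   (data.frame: gene, reason, value), `candidates` (character), plus the
#'   inputs echoed (`scores`, `thresholds`).
#' @export
select_candidates <- function(scores, ratios, annotation = NULL, region = NULL,
                              region_genes = NULL, dosage_chromosome = NULL,
                              thresholds = prioritization_thresholds()) {
  stopifnot(is.data.frame(scores),
            all(c("gene", "abs_loading", "rank") %in% names(scores)))
  th <- thresholds
  if (is.null(region_genes)) {
    if (is.null(annotation) || is.null(region))
      stop("give either region_genes or annotation + region", call. = FALSE)
    ann <- annotation
    if (!is.null(dosage_chromosome)) ann <- ann[ann$chrom == dosage_chromosome, ]
    hit <- ann$start < region[2] & ann$end > region[1]  # half-open overlap
    region_genes <- ann$gene[hit]
  }
  if (length(region_genes) == 0)
    warning("no genes in the selection region", call. = FALSE)

  sc <- scores[scores$gene %in% region_genes, , drop = FALSE]
  sc <- sc[!is.na(sc$rank) & sc$rank <= th$rank_secondary, , drop = FALSE]
  sc <- sc[order(sc$rank, sc$gene), , drop = FALSE]
  idx <- match(sc$gene, ratios$gene)
  dminus <- ratios$Dminus[idx]; dplus <- ratios$Dplus[idx]
  dremov <- ratios$Dremov[idx]
  rf <- reversion_fraction(dminus, dplus, dremov)
  tier <- ifelse(sc$rank <= th$rank_primary, "primary", "secondary")

  low <- !is.na(dminus) & dminus < th$fold_up * (1 - THRESHOLD_EPS)
  norev <- !low & (is.na(rf) | rf < th$reversion_min * (1 - THRESHOLD_EPS))
  excl <- rbind(
    if (any(low)) data.frame(gene = sc$gene[low], reason = "low_Dminus",
                             value = dminus[low], stringsAsFactors = FALSE),
    if (any(norev)) data.frame(gene = sc$gene[norev], reason = "no_reversion",
                               value = rf[norev], stringsAsFactors = FALSE))
  if (is.null(excl))
    excl <- data.frame(gene = character(0), reason = character(0),
                       value = numeric(0), stringsAsFactors = FALSE)

  shortlist <- data.frame(gene = sc$gene, rank = sc$rank, tier = tier,
                          abs_loading = sc$abs_loading, Dminus = dminus,
                          Dplus = dplus, Dremov = dremov, reversion = rf,
                          excluded = low | norev, stringsAsFactors = FALSE)
  structure(list(shortlist = shortlist, exclusions = excl,
                 candidates = shortlist$gene[!shortlist$excluded],
                 region_genes = region_genes, scores = scores,
                 thresholds = th),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate report\n")
  cat(sprintf("  region genes: %d; shortlist (rank <= %d): %d\n",
              length(x$region_genes), x$thresholds$rank_secondary,
              nrow(x$shortlist)))
  if (nrow(x$exclusions))
    for (i in seq_len(nrow(x$exclusions)))
      cat(sprintf("  excluded %s (%s, %.3g)\n", x$exclusions$gene[i],
                  x$exclusions$reason[i], x$exclusions$value[i]))
  cat(sprintf("  %d candidates: %s\n", length(x$candidates),
              paste(x$candidates, collapse = ", ")))
  invisible(x)
}

#' @export
summary.candidate_report <- function(object, ...) {
  cat("Candidate prioritization summary\n")
  if (!is.null(object$cascade)) print(object$cascade)
  print.data.frame(object$shortlist, digits = 3, row.names = FALSE)
  print(object)
  invisible(object)
}

#' Prioritize candidate genes from counts to a candidate report
#'
#' The full inference: TMM factors, ratio table, filter cascade on the
#' dosage chromosome, component-1 gene scoring of the positive-count genes
#' (per-sample log2 ratios to the control mean), and region-restricted
#' candidate selection with exclusion rules. Intermediate artifacts are kept
#' on the returned object for reporting.
#'
#' @param counts genes x samples raw count matrix.
#' @param annotation gene intervals (`gene`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param design sample-to-condition design.
#' @param region half-open interval on `dosage_chromosome` used as the
#'   selection window.
#' @param dosage_chromosome chromosome carrying the extra copy.
#' @param thresholds a [prioritization_thresholds()].
#' @param pseudocount passed to [ratio_table()].
#' @return A `candidate_report` additionally carrying `cascade`, `ratios`,
#'   `factors` and `pca`.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 3), chip = FALSE)
#' rep <- prioritize(sim$counts, sim$annotation, sim$design,
#'                   region = sim$config$critical_region,
#'                   dosage_chromosome = "chr21")
#' print(rep)
#' @export
prioritize <- function(counts, annotation, design, region, dosage_chromosome,
                       thresholds = prioritization_thresholds(),
                       pseudocount = 0.5) {
  counts <- as_count_matrix(counts)
  factors <- with_stage("normalize", tmm_factors(counts))
  ratios <- with_stage("normalize", ratio_table(counts, design,
                                                factors = factors,
                                                pseudocount = pseudocount))
  cascade <- with_stage("cascade",
    filter_cascade(counts, ratios, design, annotation, dosage_chromosome,
                   thresholds))
  S1 <- cascade$stages$S1
  if (length(S1) < 2L)
    stop("prioritize [pca]: fewer than two scored genes", call. = FALSE)
  x <- attr(ratios, "cpm")
  ctrl <- attr(ratios, "design")
  ctrl_mean <- rowMeans(x[, ctrl$sample[ctrl$condition == "cDi21"], drop = FALSE])
  pc <- pseudocount
  lr <- log2(t((x[S1, , drop = FALSE] + pc) / (ctrl_mean[S1] + pc)))
  dminus <- stats::setNames(ratios$Dminus[match(S1, ratios$gene)], S1)
  pca <- with_stage("pca", pca_gene_scores(lr, dminus_ratio = dminus))
  report <- with_stage("select",
    select_candidates(pca$scores, ratios, annotation = annotation,
                      region = region, dosage_chromosome = dosage_chromosome,
                      thresholds = thresholds))
  report$cascade <- cascade
  report$ratios <- ratios
  report$factors <- factors
  report$pca <- pca
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("prioritize [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE))
}
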