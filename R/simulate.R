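#' Simulate a complete silencing-reversion experiment
#'
#' Generates gene annotation, a count matrix over the four conditions, binned
#' H3K27me3 ChIP coverage, and the ground truth (silenced, reverter and
#' driver gene sets) under the model described in `vignette("silencing-reversion")`.
#'
#' Expected expression of a dosage-chromosome gene with baseline `b` and
#' per-gene trisomic fold `f`:
#' `Dminus = b * f`;
#' `Dplus = b * (1 + (1 - silencing_efficacy) * (f - 1))`;
#' `Dremov = Dplus` for maintained genes and
#' `Dplus + reverter_recovery * (Dminus - Dplus)` for reverters.
#' Genes on other chromosomes are condition-independent. Counts are drawn
#' from a negative binomial with the configured dispersion (exact
#' expectations when `dispersion == 0`).
#'
#' ChIP bins over silenced gene bodies on the dosage chromosome have
#' expectation `chip_background_rate * chip_enrichment_factor` in `Dplus`
#' samples; in `Dremov` the enrichment is retained at `chip_retention` of its
#' excess over background for maintained genes and absent for reverters; all
#' other bins sit at background.
#'
#' @param config a [sim_config()] object.
#' @param chip logical; also simulate binned ChIP coverage (set `FALSE` to
#'   speed up expression-only studies). The expression stream is unaffected.
#' @return An object of class `silencing_sim`: list with `counts`
#'   (genes x samples matrix), `annotation` (data.frame: gene, chrom, start,
#'   end, strand; 0-based half-open), `design` (data.frame: sample,
#'   condition, replicate), `expected` (genes x conditions expectation matrix
#'   on the relative scale), `chip_bins` (a `coverage_bins` object or NULL),
#'   `truth` (dosage chromosome, silenced/reverter/driver gene sets,
#'   per-gene baseline, enriched bins) and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = c(chrA = 20, chr21 = 30),
#'                                       critical_region = c(0, 100000),
#'                                       n_drivers = 2, seed = 7), chip = FALSE)
#' dim(sim$counts)
#' @export
simulate_experiment <- function(config, chip = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config

  ## --- annotation + per-gene parameters (sub-stream 0) -------------------
  set.seed(cfg$seed)
  chroms <- names(cfg$n_genes)
  ann <- do.call(rbind, lapply(chroms, function(ch) {
    n <- cfg$n_genes[[ch]]
    if (n == 0L) return(NULL)
    st <- gene_starts(n, cfg$gene_spacing)
    data.frame(gene = sprintf("%s_g%04d", ch, seq_len(n)), chrom = ch,
               start = st, end = st + cfg$gene_length,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann))
    ann <- data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  n_tot <- nrow(ann)
  baseline <- stats::setNames(
    stats::rlnorm(n_tot, cfg$baseline_log_mean, cfg$baseline_log_sd), ann$gene)

  on_dosage <- ann$chrom == cfg$dosage_chromosome
  dosage_genes <- ann$gene[on_dosage]

  ## per-gene trisomic fold
  fold <- stats::setNames(rep(1, n_tot), ann$gene)
  nd <- length(dosage_genes)
  if (nd > 0) {
    if (is.finite(cfg$dosage_shape)) {
      excess <- (cfg$dosage_factor - 1) *
        stats::rgamma(nd, shape = cfg$dosage_shape, rate = cfg$dosage_shape)
    } else {
      excess <- rep(cfg$dosage_factor - 1, nd)
    }
    fold[dosage_genes] <- 1 + excess
  }

  ## reverters: drivers forced into the critical region, the rest outside it
  in_region <- on_dosage & ann$start >= cfg$critical_region[1] &
    ann$end <= cfg$critical_region[2]
  region_genes <- ann$gene[in_region]
  drivers <- if (cfg$n_drivers > 0 && length(region_genes) > 0)
    sample(region_genes, min(cfg$n_drivers, length(region_genes))) else character(0)
  n_rev <- round(cfg$reverter_fraction * nd)
  outside <- setdiff(dosage_genes, region_genes)
  extra <- max(0L, n_rev - length(drivers))
  reverters <- c(drivers, if (extra > 0 && length(outside) > 0)
    sample(outside, min(extra, length(outside))) else character(0))
  if (length(drivers) > 0)
    fold[drivers] <- stats::runif(length(drivers), cfg$driver_dosage_range[1],
                                  cfg$driver_dosage_range[2])

  ## --- expectation matrix -------------------------------------------------
  conds <- cfg$conditions
  expected <- matrix(baseline, nrow = n_tot, ncol = 4,
                     dimnames = list(ann$gene, conds))
  if (nd > 0) {
    b <- baseline[dosage_genes]; f <- fold[dosage_genes]
    dminus <- b * f
    dplus <- b * (1 + (1 - cfg$silencing_efficacy) * (f - 1))
    dremov <- dplus
    rev_idx <- dosage_genes %in% reverters
    dremov[rev_idx] <- dplus[rev_idx] +
      cfg$reverter_recovery * (dminus[rev_idx] - dplus[rev_idx])
    expected[dosage_genes, "Dminus"] <- dminus
    expected[dosage_genes, "Dplus"] <- dplus
    expected[dosage_genes, "Dremov"] <- dremov
  }

  ## --- counts (sub-stream 1) ---------------------------------------------
  set.seed(cfg$seed + 1L)
  design <- data.frame(
    sample = paste(rep(conds, each = cfg$n_replicates),
                   rep(seq_len(cfg$n_replicates), length(conds)), sep = "_"),
    condition = rep(conds, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), length(conds)),
    stringsAsFactors = FALSE)
  counts <- matrix(0, nrow = n_tot, ncol = nrow(design),
                   dimnames = list(ann$gene, design$sample))
  for (j in seq_len(nrow(design))) {
    mu_rel <- expected[, design$condition[j]]
    tot <- sum(mu_rel)
    mu <- if (tot > 0) mu_rel / tot * cfg$library_size else mu_rel
    counts[, j] <- if (cfg$dispersion > 0)
      stats::rnbinom(n_tot, mu = mu, size = 1 / cfg$dispersion) else mu
  }

  ## --- ChIP coverage (sub-stream 2) ---------------------------------------
  chip_bins <- NULL
  enriched <- data.frame(chrom = character(0), bin = integer(0))
  if (isTRUE(chip) && n_tot > 0) {
    set.seed(cfg$seed + 2L)
    w <- cfg$chip_bin_width
    chrom_len <- cfg$n_genes * cfg$gene_spacing
    bins <- do.call(rbind, lapply(chroms, function(ch) {
      nb <- as.integer(ceiling(chrom_len[[ch]] / w))
      if (nb == 0L) return(NULL)
      data.frame(chrom = ch, start = (seq_len(nb) - 1L) * w,
                 end = pmin(seq_len(nb) * w, as.integer(chrom_len[[ch]])),
                 stringsAsFactors = FALSE)
    }))
    nb_tot <- nrow(bins)
    rate <- matrix(cfg$chip_background_rate, nrow = nb_tot, ncol = nrow(design),
                   dimnames = list(NULL, design$sample))
    if (nd > 0) {
      db <- bins$chrom == cfg$dosage_chromosome
      ann_d <- ann[on_dosage, ]
      ir_bins <- IRanges::IRanges(start = bins$start[db] + 1L, end = bins$end[db])
      ir_gene <- IRanges::IRanges(start = ann_d$start + 1L, end = ann_d$end)
      hit <- IRanges::findOverlaps(ir_bins, ir_gene)
      bin_gene <- ann_d$gene[S4Vectors_subjectHits(hit)]
      bin_row <- which(db)[S4Vectors_queryHits(hit)]
      is_rev <- bin_gene %in% reverters
      bg <- cfg$chip_background_rate
      ## per-gene enrichment scales with the gene's dosage response (deeper
      ## silencing <-> denser H3K27me3), with chromosome-mean fold
      ## chip_enrichment_factor when the mean dosage response is met
      rel <- if (cfg$dosage_factor > 1)
        pmax(0, (fold[bin_gene] - 1) / (cfg$dosage_factor - 1)) else 1
      enr <- bg * (1 + (cfg$chip_enrichment_factor - 1) * rel)
      keep <- bg + (enr - bg) * cfg$chip_retention
      for (j in which(design$condition == "Dplus"))
        rate[bin_row, j] <- enr
      for (j in which(design$condition == "Dremov"))
        rate[bin_row, j] <- ifelse(is_rev, bg, keep)
      enriched <- unique(data.frame(chrom = cfg$dosage_chromosome,
                                    bin = S4Vectors_queryHits(hit) - 1L))
    }
    cnt <- if (cfg$dispersion > 0)
      matrix(stats::rpois(length(rate), rate), nrow = nb_tot,
             dimnames = dimnames(rate)) else rate
    chip_bins <- new_coverage_bins(bins, cnt, w)
  }

  truth <- list(dosage_chromosome = cfg$dosage_chromosome,
                silenced_genes = dosage_genes,
                reverter_genes = sort(reverters),
                driver_genes = sort(drivers),
                per_gene_baseline = baseline,
                per_gene_fold = fold,
                chip_enriched_bins = enriched)
  structure(list(counts = counts, annotation = ann, design = design,
                 expected = expected, chip_bins = chip_bins, truth = truth,
                 config = cfg),
            class = "silencing_sim")
}

S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' @export
print.silencing_sim <- function(x, ...) {
  cat("Synthetic silencing-reversion experiment\n")
  cat(sprintf("  %d genes on %d chromosomes; %d samples (%s x %d)\n",
              nrow(x$counts), length(unique(x$annotation$chrom)),
              ncol(x$counts), paste(unique(x$design$condition), collapse = "/"),
              x$config$n_replicates))
  cat(sprintf("  dosage chromosome %s: %d genes, %d reverters (%d drivers in region)\n",
              x$truth$dosage_chromosome, length(x$truth$silenced_genes),
              length(x$truth$reverter_genes), length(x$truth$driver_genes)))
  if (!is.null(x$chip_bins))
    cat(sprintf("  ChIP: %d bins of %d bp\n", nrow(x$chip_bins$bins),
                x$chip_bins$bin_width))
  invisible(x)
}
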