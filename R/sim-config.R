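#' Configuration for a synthetic silencing-reversion experiment
#'
#' Collects the design constants of an inducible-XIST chromosome-silencing
#' experiment in an isogenic trisomic cell panel: a euploid control line
#' (`cDi21`), the trisomic untreated line (`Dminus`), the doxycycline-treated
#' silenced line (`Dplus`), and the line sampled after doxycycline withdrawal
#' (`Dremov`). Genes live on synthetic chromosomes with their own 0-based
#' half-open coordinate systems; one chromosome carries the extra copy.
#'
#' @param n_genes named integer vector, number of genes per chromosome label.
#' @param dosage_chromosome chromosome label carrying the extra copy.
#' @param dosage_factor expected mean trisomic/euploid expression ratio of
#'   genes on the dosage chromosome (three copies vs two gives 1.5).
#' @param dosage_shape Gamma shape controlling per-gene heterogeneity of the
#'   dosage response. Per-gene trisomic excess is
#'   `(dosage_factor - 1) * G` with `G ~ Gamma(shape, rate = shape)` (mean 1),
#'   so the chromosome-mean ratio stays `dosage_factor`. `Inf` gives the
#'   homogeneous response used by closed-form checks.
#' @param n_replicates replicates per condition (>= 2; the Welch stage needs
#'   at least two per group).
#' @param silencing_efficacy fraction in \[0,1\] by which treated (`Dplus`)
#'   expression of dosage-chromosome genes returns toward the euploid level;
#'   1 is complete silencing of the extra copy.
#' @param reverter_fraction fraction of dosage-chromosome genes that escape
#'   maintenance after withdrawal and move back toward trisomic levels.
#' @param reverter_recovery fraction of the silenced decrement a reverter gene
#'   recovers in `Dremov`.
#' @param driver_dosage_range range of trisomic fold-changes for planted
#'   driver genes (robustly dosage-responsive reverters seeded inside
#'   `critical_region`).
#' @param baseline_log_mean,baseline_log_sd log-scale parameters of the
#'   per-gene baseline expression distribution (lognormal).
#' @param dispersion negative-binomial dispersion of the count noise
#'   (variance `mu + dispersion * mu^2`). `0` switches the generator to
#'   noiseless expectation mode: emitted "counts" are the exact (possibly
#'   fractional) expected values, which makes closed-form checks exact.
#' @param library_size expected total read count per sample.
#' @param gene_spacing,gene_length base pairs between gene starts / gene span.
#' @param critical_region length-2 numeric, 0-based half-open interval on the
#'   dosage chromosome in which driver genes are planted (the analogue of the
#'   RUNX1--ETS2 critical segment).
#' @param n_drivers number of reverter genes forced into `critical_region`.
#' @param chip_background_rate expected H3K27me3 fragments per 100-bp bin in
#'   unenriched chromatin.
#' @param chip_enrichment_factor fold enrichment of bins over silenced gene
#'   bodies in `Dplus`.
#' @param chip_retention fraction of the `Dplus` enrichment retained in
#'   `Dremov` over maintained (non-reverter) genes.
#' @param chip_bin_width ChIP bin width in base pairs.
#' @param seed integer PRNG master seed; sub-streams for annotation,
#'   expression and ChIP are derived from it deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = c(chr1 = 600L, chr2 = 550L, chr17 = 450L, chr21 = 178L),
                       dosage_chromosome = "chr21",
                       dosage_factor = 1.5,
                       dosage_shape = 5,
                       n_replicates = 3L,
                       silencing_efficacy = 1,
                       reverter_fraction = 0.1,
                       reverter_recovery = 0.6,
                       driver_dosage_range = c(1.9, 2.3),
                       baseline_log_mean = 4,
                       baseline_log_sd = 1.2,
                       dispersion = 0.01,
                       library_size = 2e7,
                       gene_spacing = 10000L,
                       gene_length = 5000L,
                       critical_region = c(790000, 1030000),
                       n_drivers = 5L,
                       chip_background_rate = 50,
                       chip_enrichment_factor = 3,
                       chip_retention = 0.6,
                       chip_bin_width = 100L,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, dosage_chromosome = dosage_chromosome,
    dosage_factor = dosage_factor, dosage_shape = dosage_shape,
    conditions = c("cDi21", "Dminus", "Dplus", "Dremov"),
    n_replicates = as.integer(n_replicates),
    silencing_efficacy = silencing_efficacy,
    reverter_fraction = reverter_fraction,
    reverter_recovery = reverter_recovery,
    driver_dosage_range = driver_dosage_range,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion, library_size = library_size,
    gene_spacing = as.integer(gene_spacing), gene_length = as.integer(gene_length),
    critical_region = critical_region, n_drivers = as.integer(n_drivers),
    chip_background_rate = chip_background_rate,
    chip_enrichment_factor = chip_enrichment_factor,
    chip_retention = chip_retention,
    chip_bin_width = as.integer(chip_bin_width),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(what) stop("invalid sim_config: ", what, call. = FALSE)
  if (is.null(names(cfg$n_genes)) || any(names(cfg$n_genes) == ""))
    fail("n_genes must be a named vector of chromosome labels")
  if (any(cfg$n_genes < 0)) fail("n_genes must be non-negative")
  if (!cfg$dosage_chromosome %in% names(cfg$n_genes))
    fail("dosage_chromosome must be one of the chromosome labels")
  if (!is.numeric(cfg$dosage_factor) || cfg$dosage_factor <= 0)
    fail("dosage_factor must be > 0")
  if (cfg$dosage_shape <= 0) fail("dosage_shape must be > 0 (Inf allowed)")
  if (cfg$n_replicates < 2L)
    fail("n_replicates must be >= 2 (the Welch stage needs two per group)")
  for (f in c("silencing_efficacy", "reverter_fraction", "reverter_recovery",
              "chip_retention")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(paste(f, "must lie in [0, 1]"))
  }
  if (cfg$dispersion < 0) fail("dispersion must be >= 0")
  if (cfg$library_size <= 0) fail("library_size must be > 0")
  if (cfg$gene_length > cfg$gene_spacing)
    fail("gene_length must not exceed gene_spacing")
  span <- cfg$n_genes[[cfg$dosage_chromosome]] * cfg$gene_spacing
  cr <- cfg$critical_region
  if (span > 0) {
    if (length(cr) != 2L || cr[1] < 0 || cr[2] <= cr[1] || cr[2] > span)
      fail("critical_region must be a half-open interval within the dosage chromosome span")
    n_in_region <- sum(gene_starts(cfg$n_genes[[cfg$dosage_chromosome]], cfg$gene_spacing) >= cr[1] &
                       gene_starts(cfg$n_genes[[cfg$dosage_chromosome]], cfg$gene_spacing) +
                         cfg$gene_length <= cr[2])
    if (cfg$n_drivers > n_in_region)
      fail(sprintf("n_drivers (%d) exceeds the %d genes inside critical_region",
                   cfg$n_drivers, n_in_region))
  } else if (cfg$n_drivers > 0L) {
    fail("n_drivers must be 0 on an empty dosage chromosome")
  }
  if (length(cfg$driver_dosage_range) != 2L ||
      any(cfg$driver_dosage_range <= 0) ||
      cfg$driver_dosage_range[1] > cfg$driver_dosage_range[2])
    fail("driver_dosage_range must be an increasing pair of positive folds")
  if (cfg$chip_background_rate < 0 || cfg$chip_enrichment_factor <= 0)
    fail("ChIP rate parameters must be positive")
  if (abs(cfg$seed) > 2^31 - 16) fail("seed out of 32-bit range")
  invisible(cfg)
}

gene_starts <- function(n, spacing) if (n == 0L) numeric(0) else (seq_len(n) - 1) * spacing

#' @export
print.sim_config <- function(x, ...) {
  cat("Silencing-reversion simulation configuration\n")
  cat("  chromosomes:", paste(sprintf("%s (%d genes)", names(x$n_genes), x$n_genes),
                              collapse = ", "), "\n")
  cat(sprintf("  dosage chromosome: %s, mean fold %.3g (Gamma shape %.3g)\n",
              x$dosage_chromosome, x$dosage_factor, x$dosage_shape))
  cat(sprintf("  conditions: %s x %d replicates\n",
              paste(x$conditions, collapse = "/"), x$n_replicates))
  cat(sprintf("  silencing efficacy %.2f; reverters %.2f of chromosome, recovery %.2f\n",
              x$silencing_efficacy, x$reverter_fraction, x$reverter_recovery))
  cat(sprintf("  %d drivers in region [%s, %s)\n", x$n_drivers,
              format(x$critical_region[1], big.mark = ","),
              format(x$critical_region[2], big.mark = ",")))
  cat(sprintf("  NB dispersion %.3g, library size %.3g, seed %d\n",
              x$dispersion, x$library_size, x$seed))
  invisible(x)
}
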