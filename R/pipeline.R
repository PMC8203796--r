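#' Pipeline configuration
#'
#' One object holding everything an end-to-end run needs: either a
#' [sim_config()] (simulate-then-analyze mode) or an input directory in the
#' on-disk dialect of [write_dataset()], plus the analysis parameters.
#'
#' @param simulation a `sim_config`, or NULL to read from `input_dir`.
#' @param input_dir directory with `counts.tsv`, `design.tsv`, `genes.bed`
#'   (and optionally `chip_*.bedGraph`).
#' @param out_dir directory for artifacts (created on run).
#' @param thresholds a [prioritization_thresholds()].
#' @param window a [window_params()].
#' @param region selection region; defaults to the simulation's critical
#'   region in simulate mode.
#' @param dosage_chromosome defaults to the simulation's dosage chromosome.
#' @param pseudocount passed to [ratio_table()].
#' @param chip run the ChIP stages when coverage is available.
#' @param seed integer seed applied before simulation.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL, out_dir,
                            thresholds = prioritization_thresholds(),
                            window = window_params(), region = NULL,
                            dosage_chromosome = NULL, pseudocount = 0.5,
                            chip = TRUE, seed = NULL) {
  if (is.null(simulation) && is.null(input_dir))
    stop("give a simulation config or an input directory", call. = FALSE)
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "sim_config"))
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
    if (is.null(region)) region <- simulation$critical_region
    if (is.null(dosage_chromosome))
      dosage_chromosome <- simulation$dosage_chromosome
  }
  if (is.null(region) || is.null(dosage_chromosome))
    stop("region and dosage_chromosome are required in file mode", call. = FALSE)
  structure(list(simulation = simulation, input_dir = input_dir,
                 out_dir = out_dir, thresholds = thresholds, window = window,
                 region = region, dosage_chromosome = dosage_chromosome,
                 pseudocount = pseudocount, chip = isTRUE(chip), seed = seed),
            class = "pipeline_config")
}

artifact_header <- function() {
  sprintf("# trisilence %s",
          as.character(utils::packageVersion("trisilence")))
}

write_tsv_artifact <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full silencing-reversion pipeline
#'
#' Simulate (optional) -> normalize -> chromosome summaries -> prioritize ->
#' ChIP integrate; writes the standard artifacts (`ratio_table.tsv`,
#' `chromosome_summary.tsv`, `candidates.tsv`, `candidate_report.json`,
#' `gene_chip_scores.tsv`, `integration.tsv`) and returns a `run_report`.
#' Reruns with the same configuration and seed reproduce the artifacts
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input_dir)) {
    ds <- read_dataset(config$input_dir, chip = config$chip)
  } else {
    ds <- simulate_experiment(config$simulation, chip = config$chip)
  }
  if (is.null(ds$annotation))
    stop("configuration error: no gene annotation available", call. = FALSE)
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE))
    stop("cannot create output directory", call. = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  warnings <- character(0)

  report <- prioritize(ds$counts, ds$annotation, ds$design,
                       region = config$region,
                       dosage_chromosome = config$dosage_chromosome,
                       thresholds = config$thresholds,
                       pseudocount = config$pseudocount)
  chrsum <- chromosome_ratio_summary(report$ratios, ds$annotation,
                                     dosage_chromosome = config$dosage_chromosome)

  integration <- NULL
  chip_scores <- NULL
  if (config$chip && !is.null(ds$chip_bins)) {
    chip_scores <- gene_accumulation(ds$chip_bins, ds$annotation,
                                     params = config$window,
                                     design = ds$design)
    # the joint view targets the silenced chromosome, as in the study
    rat21 <- report$ratios[
      report$ratios$gene %in%
        ds$annotation$gene[ds$annotation$chrom == config$dosage_chromosome], ,
      drop = FALSE]
    class(rat21) <- class(report$ratios)
    integration <- integrate_expression_chip(rat21, chip_scores,
                                             ds$design,
                                             fdr_alpha = config$window$fdr_alpha)
  } else if (config$chip) {
    warnings <- c(warnings, "no ChIP coverage available; ChIP stages skipped")
  }

  rt <- as.data.frame(report$ratios)
  rt$chrom <- ds$annotation$chrom[match(rt$gene, ds$annotation$gene)]
  write_tsv_artifact(rt[, c("gene", "chrom", setdiff(names(rt), c("gene", "chrom")))],
                     p("ratio_table.tsv"))
  write_tsv_artifact(as.data.frame(chrsum), p("chromosome_summary.tsv"))
  write_tsv_artifact(report$shortlist, p("candidates.tsv"))
  if (!is.null(chip_scores)) {
    sc <- data.frame(gene = rownames(chip_scores$scores), chip_scores$scores,
                     check.names = FALSE)
    write_tsv_artifact(sc, p("gene_chip_scores.tsv"))
    write_tsv_artifact(as.data.frame(integration), p("integration.tsv"))
  }

  stage_counts <- lengths(report$cascade$stages)
  rr <- structure(list(
    version = as.character(utils::packageVersion("trisilence")),
    config = config,
    stage_counts = stage_counts,
    chromosome_summary = chrsum,
    candidates = report$candidates,
    exclusions = report$exclusions,
    report = report,
    integration = integration,
    spearman = if (!is.null(integration)) attr(integration, "spearman") else NA_real_,
    warnings = warnings), class = "run_report")
  jsonlite::write_json(report_as_list(rr), p("candidate_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rr
}

report_as_list <- function(rr) {
  list(version = rr$version,
       config = list(region = rr$config$region,
                     dosage_chromosome = rr$config$dosage_chromosome,
                     thresholds = unclass(rr$config$thresholds),
                     pseudocount = rr$config$pseudocount,
                     seed = rr$config$seed),
       stage_counts = as.list(rr$stage_counts),
       candidates = as.list(rr$candidates),
       exclusions = if (nrow(rr$exclusions))
         lapply(seq_len(nrow(rr$exclusions)), function(i)
           list(gene = rr$exclusions$gene[i],
                reason = rr$exclusions$reason[i],
                value = rr$exclusions$value[i])) else list(),
       chromosome_means = lapply(seq_len(nrow(rr$chromosome_summary)), function(i)
         list(chrom = rr$chromosome_summary$chrom[i],
              Dminus = rr$chromosome_summary$mean_Dminus[i],
              Dplus = rr$chromosome_summary$mean_Dplus[i],
              Dremov = rr$chromosome_summary$mean_Dremov[i])),
       spearman = rr$spearman,
       warnings = as.list(rr$warnings))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Silencing-reversion pipeline report (trisilence", x$version, ")\n")
  cat("  cascade:", paste(sprintf("%s=%d", names(x$stage_counts),
                                  x$stage_counts), collapse = " "), "\n")
  cat(sprintf("  %d candidates: %s\n", length(x$candidates),
              paste(x$candidates, collapse = ", ")))
  if (!is.na(x$spearman))
    cat(sprintf("  expression-H3K27me3 Spearman: %.3f\n", x$spearman))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Serialize a run report
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output file.
#' @param format one of `"json"`, `"tsv"`, `"markdown"`. JSON round-trips via
#'   [jsonlite::read_json()]; the human-readable formats list the cascade
#'   counts in stage order and every exclusion with its reason.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv", "markdown")) {
  stopifnot(inherits(report, "run_report"))
  format <- match.arg(format)
  lst <- report_as_list(report)
  if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "tsv") {
    df <- data.frame(key = c(paste0("stage_", names(report$stage_counts)),
                             "n_candidates", "candidates"),
                     value = c(report$stage_counts,
                               length(report$candidates),
                               paste(report$candidates, collapse = ",")),
                     stringsAsFactors = FALSE)
    write_tsv_artifact(df, path)
  } else {
    lines <- c(sprintf("# Silencing-reversion run (trisilence %s)", report$version),
               "", "## Cascade",
               sprintf("- %s: %d genes", names(report$stage_counts),
                       report$stage_counts),
               "", "## Candidates",
               if (length(report$candidates))
                 sprintf("- %s", report$candidates)
               else "0 candidates",
               "", "## Exclusions",
               if (nrow(report$exclusions))
                 sprintf("- %s excluded (%s, value %.4g)",
                         report$exclusions$gene, report$exclusions$reason,
                         report$exclusions$value)
               else "- none")
    writeLines(lines, path)
  }
  invisible(path)
}
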