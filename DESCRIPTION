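Package: trisilence
Title: Dosage, Silencing and Reversion Analysis for XIST-Mediated Trisomy Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of chromosome-scale transcriptional silencing and its
    reversion in isogenic trisomic cell lines carrying an inducible XIST
    transgene. From gene-level read counts across four conditions (euploid
    control, trisomic untreated, silenced, and silencing-withdrawn) the
    package computes TMM-normalized expression ratios, chromosome-level
    silencing summaries (Kruskal-Wallis with Bonferroni correction,
    hierarchical clustering), and a candidate-gene prioritization combining a
    filter cascade (fold-change, silencing response, Welch test, reversion)
    with principal-component gene scoring and a genomic-region restriction.
    Windowed H3K27me3 ChIP coverage is integrated with expression via
    Benjamini-Hochberg-controlled differential windows and gene-body
    accumulation scores. A synthetic-data generator emulates the full
    experimental design so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
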