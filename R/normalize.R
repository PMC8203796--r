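#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count matrices, robust to composition
#' bias. For each sample versus a reference sample, per-gene log2 ratios (M)
#' and average log2 abundances (A) are computed after library-size scaling;
#' genes with a zero count in either sample are excluded; M is trimmed
#' two-sided by `trim_m` and A by `trim_a`; the factor is the exponentiated
#' precision-weighted mean of the surviving M values. Factors are rescaled to
#' geometric mean 1 (effective library size = raw library size x factor).
#'
#' @param counts non-negative genes x samples matrix with unique dimnames.
#' @param reference_sample sample id to use as reference; default picks the
#'   sample whose upper-quartile count fraction is closest to the
#'   across-sample mean upper quartile (deterministic).
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05, the published TMM defaults).
#' @param weighted use inverse asymptotic-variance (precision) weights.
#' @return Named numeric vector of factors (geometric mean 1), with the
#'   chosen reference in `attr(, "reference")`.
#' @examples
#' m <- matrix(rpois(40, 50), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' tmm_factors(m)
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05, weighted = TRUE) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2L)
    stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("degenerate library: sample(s) with zero total count: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)

  if (is.null(reference_sample)) {
    f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    reference_sample <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  }
  if (!reference_sample %in% colnames(counts))
    stop("unknown reference sample: ", reference_sample, call. = FALSE)

  ref <- counts[, reference_sample]
  nref <- lib[[reference_sample]]
  f <- vapply(colnames(counts), function(s) {
    obs <- counts[, s]; nobs <- lib[[s]]
    keep <- obs > 0 & ref > 0
    if (!any(keep)) return(1)
    yo <- obs[keep] / nobs; yr <- ref[keep] / nref
    M <- log2(yo / yr)
    A <- 0.5 * log2(yo * yr)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(use)) return(1)
    if (weighted) {
      w <- (nobs - obs[keep]) / (nobs * obs[keep]) +
           (nref - ref[keep]) / (nref * ref[keep])
      w[w <= 0] <- min(w[w > 0], 1e-12)
      fac <- 2^(sum(M[use] / w[use]) / sum(1 / w[use]))
    } else {
      fac <- 2^mean(M[use])
    }
    if (!is.finite(fac) || fac <= 0) 1 else fac
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  attr(f, "reference") <- reference_sample
  f
}

as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or sample identifiers", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  counts
}

check_design <- function(counts, design, need = NULL) {
  if (!all(c("sample", "condition") %in% names(design)))
    stop("design needs 'sample' and 'condition' columns", call. = FALSE)
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$sample))
    stop("duplicated sample rows in design", call. = FALSE)
  for (cond in need)
    if (!cond %in% design$condition)
      stop("design lacks condition: ", cond, call. = FALSE)
  invisible(design[design$sample %in% colnames(counts), , drop = FALSE])
}

#' Normalized counts per million
#'
#' @param counts genes x samples count matrix.
#' @param factors TMM factors as from [tmm_factors()]; default computes them.
#' @return Matrix of `count / (library size x factor) x 1e6`.
#' @export
cpm <- function(counts, factors = tmm_factors(counts)) {
  counts <- as_count_matrix(counts)
  lib <- colSums(counts)
  t(t(counts) / (lib * factors[colnames(counts)])) * 1e6
}

#' Per-gene per-condition expression ratios relative to the euploid control
#'
#' Per-sample normalized abundances (CPM under TMM factors) are averaged
#' within each condition; the ratio is the condition mean over the `cDi21`
#' control mean, with a pseudocount added to both means. Genes with a zero
#' control mean and zero pseudocount get `NA` (undefined, not infinite).
#'
#' @param counts genes x samples count matrix.
#' @param design data.frame with `sample` and `condition` columns covering
#'   all samples; conditions must include `cDi21`.
#' @param factors optional TMM factors; computed when NULL.
#' @param pseudocount CPM added to each condition mean before the ratio
#'   (default 0.5; set 0 for exact closed-form checks).
#' @return A `ratio_table`: data.frame with columns `gene`, `cDi21`,
#'   `Dminus`, `Dplus`, `Dremov` (those conditions present), carrying the
#'   per-sample CPM matrix in `attr(, "cpm")` and the design in
#'   `attr(, "design")`.
#' @export
ratio_table <- function(counts, design, factors = NULL, pseudocount = 0.5) {
  counts <- as_count_matrix(counts)
  design <- check_design(counts, design, need = "cDi21")
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (is.null(factors)) factors <- tmm_factors(counts)
  x <- cpm(counts, factors)
  conds <- unique(design$condition)
  means <- vapply(conds, function(cc) {
    rowMeans(x[, design$sample[design$condition == cc], drop = FALSE])
  }, numeric(nrow(x)))
  means <- matrix(means, nrow = nrow(x), dimnames = list(rownames(x), conds))
  ctrl <- means[, "cDi21"]
  ratios <- (means + pseudocount) / (ctrl + pseudocount)
  undef <- ctrl + pseudocount == 0
  ratios[undef, ] <- NA_real_
  out <- data.frame(gene = rownames(x), ratios, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cpm") <- x
  attr(out, "design") <- design
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Genes with positive read counts in the trisomic (XIST) lines
#'
#' Returns the genes with a raw count of at least one read in at least one
#' sample of the treated, untreated or withdrawal lines. By the chosen
#' reading of "positive read counts in at least one of the APC lines",
#' control-only expression does not qualify; set `include_control = TRUE`
#' for the permissive rule.
#'
#' @param counts genes x samples count matrix.
#' @param design sample-to-condition design table.
#' @param include_control also count `cDi21` samples.
#' @return Character vector of gene ids (deterministic, input order).
#' @export
positive_count_filter <- function(counts, design, include_control = FALSE) {
  counts <- as_count_matrix(counts)
  design <- check_design(counts, design)
  keep <- if (include_control) design$sample
          else design$sample[design$condition != "cDi21"]
  sub <- counts[, keep, drop = FALSE]
  rownames(counts)[rowSums(sub >= 1) > 0]
}
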