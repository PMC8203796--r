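# Small configurations and toy data built in code; no stored fixtures beyond
# the packaged worked-example table.

small_config <- function(seed = 1, ...) {
  sim_config(n_genes = c(chrA = 60L, chr21 = 40L),
             critical_region = c(0, 120000), n_drivers = 3L,
             seed = seed, ...)
}

# homogeneous, noiseless configuration for closed-form checks
noiseless_config <- function(seed = 1, ...) {
  sim_config(dispersion = 0, dosage_shape = Inf,
             driver_dosage_range = c(1.5, 1.5), seed = seed, ...)
}

toy_design <- function(samples, conditions) {
  data.frame(sample = samples, condition = conditions,
             replicate = stats::ave(seq_along(samples), conditions,
                                    FUN = seq_along),
             stringsAsFactors = FALSE)
}

toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force TMM oracle: explicit sort-based trimming and
# explicit precision weights, no shared code with tmm_factors()
oracle_tmm <- function(counts, ref) {
  lib <- colSums(counts)
  fac <- sapply(colnames(counts), function(s) {
    o <- counts[, s]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[[s]]) / (r / lib[[ref]]))
    A <- 0.5 * log2((o / lib[[s]]) * (r / lib[[ref]]))
    n <- length(M)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    rm <- rank(M, ties.method = "first"); ra <- rank(A, ties.method = "first")
    use <- which(rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a)
    if (!length(use)) return(1)
    w <- (lib[[s]] - o) / (lib[[s]] * o) + (lib[[ref]] - r) / (lib[[ref]] * r)
    2^(sum(M[use] / w[use]) / sum(1 / w[use]))
  })
  fac / exp(mean(log(fac)))
}

# exhaustive Benjamini-Hochberg step-up definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j_set <- which(rank(p, ties.method = "first") >= rank(p, ties.method = "first")[i])
    # direct definition: q_i = min over sorted positions j >= position(i)
    pos <- which(ord == i)
    q[i] <- min(1, min(p[ord[pos:n]] * n / (pos:n)))
  }
  q
}

# textbook Kruskal-Wallis H with tie correction
oracle_kw <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(as.integer(factor(groups)))) -
    3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}
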