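test_that("read extension and binning arithmetic is exact", {
  gs <- c(chrA = 1000)
  # plus-strand read with 5' end at 0, extension 300, 100-bp bins
  rd <- list(s1 = data.frame(chrom = "chrA", start = 0, end = 76, strand = "+"))
  cb <- bin_coverage(rd, gs)
  expect_equal(cb$counts[1:4, "s1"], c(1, 1, 1, 0))
  # minus-strand read with 5' end at 350 covers [50, 350)
  rd2 <- list(s1 = data.frame(chrom = "chrA", start = 274, end = 350, strand = "-"))
  cb2 <- bin_coverage(rd2, gs)
  expect_equal(cb2$counts[1:5, "s1"], c(1, 1, 1, 1, 0))
  # empty read set gives all-zero bins
  cb3 <- bin_coverage(list(s1 = data.frame(chrom = character(0),
                                           start = numeric(0),
                                           end = numeric(0),
                                           strand = character(0))), gs)
  expect_true(all(cb3$counts == 0))
})

test_that("reads past the chromosome end are clipped and counted", {
  gs <- c(chrA = 500)
  rd <- list(s1 = data.frame(chrom = "chrA", start = c(0, 450),
                             end = c(76, 500), strand = "+"))
  cb <- bin_coverage(rd, gs)
  expect_equal(attr(cb, "clipped")[["s1"]], 1L)
  expect_equal(unname(cb$counts[5, "s1"]), 1)  # [400,500) hit by the clipped read
})

test_that("duplicate placements collapse unless dedup is off", {
  gs <- c(chrA = 1000)
  rd <- list(s1 = data.frame(chrom = "chrA", start = c(100, 100, 100),
                             end = c(176, 176, 176), strand = "+"))
  expect_equal(max(bin_coverage(rd, gs)$counts), 1)
  expect_equal(max(bin_coverage(rd, gs, dedup = FALSE)$counts), 3)
})

test_that("total bin increments match total extended read bins", {
  # conservation: each read increments exactly the bins it overlaps
  set.seed(10)
  gs <- c(chrA = 10000)
  st <- sample(0:9000, 50)
  rd <- list(s1 = data.frame(chrom = "chrA", start = st, end = st + 76,
                             strand = sample(c("+", "-"), 50, TRUE)))
  rd$s1 <- rd$s1[!duplicated(rd$s1[c("start", "strand")]), ]
  cb <- bin_coverage(rd, gs, params = window_params(read_extension = 300))
  five <- ifelse(rd$s1$strand == "-", rd$s1$end, rd$s1$start)
  s <- pmax(0, ifelse(rd$s1$strand == "-", five - 300, five))
  e <- pmin(10000, s + 300)
  expected_bins <- sum(floor((e - 1) / 100) - floor(s / 100) + 1)
  expect_equal(sum(cb$counts), expected_bins)
})

test_that("BH q-values match the exhaustive step-up definition", {
  expect_equal(benjamini_hochberg(0.01), 0.01)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(6)
  for (i in 1:30) {
    p <- round(runif(sample(1:12, 1)), 3)
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), info = paste("case", i))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # non-decreasing in sorted order
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("identical groups yield no significant windows", {
  set.seed(3)
  cnt <- matrix(rpois(600 * 6, 40), 600, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  cnt[, 4:6] <- cnt[, 1:3]
  bins <- trisilence:::new_coverage_bins(
    data.frame(chrom = "c", start = (0:599) * 100, end = (1:600) * 100),
    cnt, 100L)
  wd <- differential_windows(bins, paste0("s", 1:3), paste0("s", 4:6))
  expect_false(any(wd$significant))
})

test_that("all-zero coverage is an empty result with a warning", {
  bins <- trisilence:::new_coverage_bins(
    data.frame(chrom = "c", start = 0, end = 100),
    matrix(0, 1, 4, dimnames = list(NULL, paste0("s", 1:4))), 100L)
  expect_warning(wd <- differential_windows(bins, c("s1", "s2"), c("s3", "s4")),
                 "all-zero")
  expect_equal(nrow(wd), 0L)
})

test_that("single-bin gene accumulation equals its count per million", {
  bins <- trisilence:::new_coverage_bins(
    data.frame(chrom = "c", start = (0:9) * 100, end = (1:10) * 100),
    matrix(c(rep(0, 3), 7, rep(0, 6)), 10, 1, dimnames = list(NULL, "s1")),
    100L)
  ann <- data.frame(gene = "g", chrom = "c", start = 300, end = 400,
                    strand = "+")
  gs <- gene_accumulation(bins, ann,
                          params = window_params(flank_upstream = 1))
  # depth is 7, so 7 reads/7 total * 1e6 per million
  expect_equal(unname(gs$scores["g", "s1"]), 7 / 7 * 1e6)
})

test_that("accumulation is strand-symmetric under coordinate mirroring", {
  set.seed(11)
  L <- 5000
  cnt <- matrix(rpois(50, 20), 50, 1, dimnames = list(NULL, "s1"))
  bins <- trisilence:::new_coverage_bins(
    data.frame(chrom = "c", start = (0:49) * 100, end = (1:50) * 100),
    cnt, 100L)
  ann_plus <- data.frame(gene = "g", chrom = "c", start = 2130, end = 3270,
                         strand = "+")
  # mirrored track and gene: x -> L - x, strand flipped
  bins_m <- trisilence:::new_coverage_bins(
    data.frame(chrom = "c", start = (0:49) * 100, end = (1:50) * 100),
    cnt[50:1, , drop = FALSE], 100L)
  ann_minus <- data.frame(gene = "g", chrom = "c", start = L - 3270,
                          end = L - 2130, strand = "-")
  a <- gene_accumulation(bins, ann_plus)$scores["g", "s1"]
  b <- gene_accumulation(bins_m, ann_minus)$scores["g", "s1"]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("genes on unknown chromosomes are skipped with a record", {
  bins <- trisilence:::new_coverage_bins(
    data.frame(chrom = "c", start = 0, end = 100),
    matrix(5, 1, 1, dimnames = list(NULL, "s1")), 100L)
  ann <- data.frame(gene = c("good", "lost"), chrom = c("c", "cZ"),
                    start = 0, end = 100, strand = "+")
  gs <- gene_accumulation(bins, ann)
  expect_equal(gs$skipped, "lost")
  expect_equal(rownames(gs$scores), "good")
})

test_that("integration classifies by the two-thirds decrease rule", {
  rt <- data.frame(gene = c("hit", "mild", "flat"), cDi21 = 1,
                   Dminus = c(1, 1, 1), Dplus = c(0.2, 0.5, 1),
                   Dremov = c(0.3, 0.6, 1), stringsAsFactors = FALSE)
  class(rt) <- c("ratio_table", "data.frame")
  samples <- paste0(rep(c("Dplus", "Dminus"), each = 3), "_", 1:3)
  design <- toy_design(samples, rep(c("Dplus", "Dminus"), each = 3))
  acc <- rbind(hit = c(50, 52, 51, 5, 6, 5),
               mild = c(50, 49, 51, 5, 5, 6),
               flat = c(5, 6, 5, 5, 6, 5))
  colnames(acc) <- samples
  chip <- structure(list(scores = acc, condition_means = NULL,
                         skipped = character(0)),
                    class = "gene_chip_scores")
  ic <- integrate_expression_chip(rt, chip, design)
  expect_true(ic$classified[ic$gene == "hit"])
  expect_false(ic$classified[ic$gene == "mild"])   # ratio 0.5 > 1/3
  expect_false(ic$classified[ic$gene == "flat"])
  # no change anywhere classifies nothing
  chip0 <- chip; chip0$scores[] <- 5
  rt0 <- rt; rt0$Dplus <- 1; rt0$Dremov <- 1
  class(rt0) <- class(rt)
  ic0 <- integrate_expression_chip(rt0, chip0, design)
  expect_false(any(ic0$classified))
})

test_that("silenced genes gain H3K27me3 and integration is anti-correlated", {
  ok <- vapply(1:3, function(s) {
    sim <- simulate_experiment(sim_config(seed = 600 + s))
    gs <- gene_accumulation(sim$chip_bins, sim$annotation,
                            design = sim$design)
    sil <- sim$truth$silenced_genes
    gain <- mean(gs$condition_means[sil, "Dplus"] >
                 gs$condition_means[sil, "Dminus"])
    rt <- ratio_table(sim$counts, sim$design)
    rt21 <- rt[rt$gene %in% sil, ]; class(rt21) <- class(rt)
    ic <- integrate_expression_chip(rt21, gs, sim$design)
    c(gain = gain, rho = attr(ic, "spearman"))
  }, numeric(2))
  expect_true(all(ok["gain", ] >= 0.95))
  expect_true(all(ok["rho", ] < -0.3))
})
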