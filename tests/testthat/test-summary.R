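make_ratio_table <- function(genes, dminus, dplus, dremov) {
  rt <- data.frame(gene = genes, cDi21 = 1, Dminus = dminus, Dplus = dplus,
                   Dremov = dremov, stringsAsFactors = FALSE)
  class(rt) <- c("ratio_table", "data.frame")
  rt
}

test_that("unit ratios give zero log-ratios and a non-significant test", {
  rt <- make_ratio_table(paste0("g", 1:10), 1, 1, 1)
  ann <- data.frame(gene = rt$gene, chrom = rep(c("c1", "c2"), each = 5))
  s <- suppressWarnings(chromosome_ratio_summary(rt, ann))
  expect_equal(s$logmean_Dminus, c(0, 0))
  expect_equal(s$mean_Dplus, c(1, 1))
  expect_true(all(is.na(s$p_value) | s$p_bonferroni == 1))
})

test_that("noiseless dosage chromosome shows the expected line means", {
  sim <- simulate_experiment(noiseless_config(seed = 2), chip = FALSE)
  rt <- ratio_table(sim$counts, sim$design, pseudocount = 0)
  s <- chromosome_ratio_summary(rt, sim$annotation,
                                dosage_chromosome = "chr21")
  i <- which(s$chrom == "chr21")
  expect_equal(s$mean_Dminus[i], 1.5, tolerance = 1e-6)
  expect_equal(s$mean_Dplus[i], 1.0, tolerance = 1e-6)
  # withdrawal mean sits between silenced and trisomic levels
  expect_gt(s$mean_Dremov[i], 1.0)
  expect_lt(s$mean_Dremov[i], 1.5)
  expect_true(all(abs(s$mean_Dminus[-i] - 1) < 1e-6))
  expect_true(s$dosage[i])
  # the across-line difference is significant on the dosage chromosome only
  expect_lt(s$p_bonferroni[i], 0.05)
})

test_that("Kruskal-Wallis matches the textbook rank formula on toys", {
  set.seed(5)
  for (i in 1:10) {
    vals <- round(runif(24, 0, 4), 2)
    grp <- rep(c("a", "b", "c"), each = 8)
    kw <- stats::kruskal.test(vals, factor(grp))
    expect_equal(unname(kw$statistic), oracle_kw(vals, grp), tolerance = 1e-10)
  }
  # and through the summary: three chromosomes, hand-assigned ratios
  rt <- make_ratio_table(paste0("g", 1:9),
                         dminus = c(2, 4, 8, 1, 1, 1, 2, 2, 2),
                         dplus = c(1, 2, 4, 1, 1, 1, 2, 2, 2),
                         dremov = c(2, 2, 2, 1, 1, 1, 2, 2, 2))
  ann <- data.frame(gene = rt$gene, chrom = rep(c("cA", "cB", "cC"), each = 3))
  s <- chromosome_ratio_summary(rt, ann)
  iA <- which(s$chrom == "cA")
  lr <- attr(s, "logratios")$cA
  expect_equal(s$kw_stat[iA],
               oracle_kw(unlist(lr), rep(names(lr), each = 3)),
               tolerance = 1e-10)
  expect_true(all(s$p_bonferroni >= s$p_value, na.rm = TRUE))
  expect_true(all(s$p_bonferroni <= 1, na.rm = TRUE))
})

test_that("chromosomes with fewer than two genes are summarised untested", {
  rt <- make_ratio_table(c("g1", "g2", "g3"), c(1, 2, 3), c(1, 1, 1), c(1, 1, 2))
  ann <- data.frame(gene = rt$gene, chrom = c("solo", "duo", "duo"))
  s <- chromosome_ratio_summary(rt, ann)
  expect_true(is.na(s$kw_stat[s$chrom == "solo"]))
  expect_false(is.na(s$kw_stat[s$chrom == "duo"]))
})

test_that("identical profiles merge at height zero", {
  rt <- make_ratio_table(c("a", "b", "c"),
                         dminus = c(2, 2, 8), dplus = c(1, 1, 1),
                         dremov = c(1.5, 1.5, 1))
  cl <- cluster_chr21_genes(rt)
  expect_equal(min(cl$height), 0)
  first <- cl$merge[1, ]
  expect_setequal(cl$labels[-first], c("a", "b"))
})

test_that("a reverter among maintained genes is the last-merged singleton", {
  # brute force over three points: the reverter is farthest from the pair
  rt <- make_ratio_table(c("kept1", "kept2", "rev"),
                         dminus = c(1.5, 1.52, 1.5),
                         dplus = c(1.0, 1.01, 1.0),
                         dremov = c(1.0, 1.01, 1.4))
  cl <- cluster_chr21_genes(rt, linkage_method = "average",
                            distance_metric = "euclidean")
  expect_equal(cl$merge[2, 1], -match("rev", cl$labels))
  expect_equal(length(cl$height), 2L)
  expect_gt(cl$height[2], cl$height[1])
})

test_that("clustering is invariant to gene input order", {
  sim <- simulate_experiment(small_config(seed = 13), chip = FALSE)
  rt <- ratio_table(sim$counts, sim$design)
  d21 <- sim$annotation$gene[sim$annotation$chrom == "chr21"]
  sub <- rt[rt$gene %in% d21, ]
  class(sub) <- class(rt)
  cl1 <- cluster_chr21_genes(sub)
  set.seed(3)
  sub2 <- sub[sample(nrow(sub)), ]
  class(sub2) <- class(rt)
  cl2 <- cluster_chr21_genes(sub2)
  expect_identical(cl1$order, cl2$order)
  expect_equal(cl1$height, cl2$height)
})

test_that("reverters concentrate in one flank of the leaf ordering", {
  pvals <- sapply(1:5, function(s) {
    sim <- simulate_experiment(sim_config(seed = 100 + s), chip = FALSE)
    rt <- ratio_table(sim$counts, sim$design)
    d21 <- sim$annotation$gene[sim$annotation$chrom == "chr21"]
    sub <- rt[rt$gene %in% d21, ]
    class(sub) <- class(rt)
    cl <- cluster_chr21_genes(sub)
    pos <- match(sim$truth$reverter_genes, cl$order)
    other <- setdiff(seq_along(cl$order), pos)
    # two-sided rank-sum: reverter leaf positions are not exchangeable
    stats::wilcox.test(pos, other)$p.value
  })
  expect_lt(median(pvals), 0.05)
})
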