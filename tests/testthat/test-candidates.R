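test_that("the published worked example is reproduced verbatim", {
  fx <- load_table1_fixture()
  rep <- select_candidates(fx$scores, fx$ratios, region_genes = fx$region_genes)
  expect_setequal(rep$shortlist$gene,
                  c("DYRK1A", "DSCR3", "HLCS", "MORC3", "PIGP", "CBR3", "SETD4"))
  expect_setequal(rep$candidates, c("DYRK1A", "DSCR3", "HLCS", "PIGP"))
  ex <- rep$exclusions
  expect_equal(ex$reason[ex$gene == "MORC3"], "low_Dminus")
  expect_equal(ex$value[ex$gene == "MORC3"], 1.29)
  expect_equal(ex$reason[ex$gene == "SETD4"], "low_Dminus")
  expect_equal(ex$value[ex$gene == "SETD4"], 1.32)
  expect_equal(ex$reason[ex$gene == "CBR3"], "no_reversion")
  expect_lt(ex$value[ex$gene == "CBR3"], 0.1)  # (1.51-1.52)/(2.24-1.52)
  # the printed score ordering is preserved
  expect_true(fx$scores$abs_loading[fx$scores$gene == "DYRK1A"] >
              fx$scores$abs_loading[fx$scores$gene == "DSCR3"])
  expect_true(fx$scores$abs_loading[fx$scores$gene == "DSCR3"] >
              fx$scores$abs_loading[fx$scores$gene == "HLCS"])
  # rank tiers: the three top-ten genes are primary-tier
  sl <- rep$shortlist
  expect_setequal(sl$gene[sl$tier == "primary"], c("DYRK1A", "DSCR3", "HLCS"))
})

test_that("a region covering no genes yields an empty report with a warning", {
  fx <- load_table1_fixture()
  expect_warning(
    rep <- select_candidates(fx$scores, fx$ratios, region_genes = character(0)),
    "no genes")
  expect_length(rep$candidates, 0)
  expect_equal(nrow(rep$shortlist), 0L)
})

test_that("region membership uses half-open base-pair overlap", {
  sc <- data.frame(gene = c("a", "b", "c"), loading = c(0.9, 0.3, 0.2),
                   abs_loading = c(0.9, 0.3, 0.2), rank = 1:3,
                   stringsAsFactors = FALSE)
  rt <- data.frame(gene = c("a", "b", "c"), cDi21 = 1, Dminus = 2,
                   Dplus = 1, Dremov = 1.8, stringsAsFactors = FALSE)
  class(rt) <- c("ratio_table", "data.frame")
  ann <- data.frame(gene = c("a", "b", "c"), chrom = "chr21",
                    start = c(0, 100, 200), end = c(100, 200, 300))
  # region [100, 200): touches b only; a ends at 100 (exclusive), c starts at 200
  rep <- select_candidates(sc, rt, annotation = ann, region = c(100, 200),
                           dosage_chromosome = "chr21")
  expect_equal(rep$shortlist$gene, "b")
  # one-base overlaps count
  rep2 <- select_candidates(sc, rt, annotation = ann, region = c(99, 201),
                            dosage_chromosome = "chr21")
  expect_setequal(rep2$shortlist$gene, c("a", "b", "c"))
})

test_that("end-to-end prioritization is deterministic and recovers noiseless drivers", {
  # zero count noise with the default heterogeneous dosage response: every
  # rule is decided by its closed-form expectation
  cfg <- sim_config(dispersion = 0, seed = 44)
  sim <- simulate_experiment(cfg, chip = FALSE)
  r1 <- prioritize(sim$counts, sim$annotation, sim$design,
                   region = cfg$critical_region, dosage_chromosome = "chr21",
                   pseudocount = 0)
  r2 <- prioritize(sim$counts, sim$annotation, sim$design,
                   region = cfg$critical_region, dosage_chromosome = "chr21",
                   pseudocount = 0)
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$shortlist, r2$shortlist)
  # without noise the candidate set is exactly the planted drivers: drivers
  # pass every rule, and region non-reverters fail the reversion exclusion
  expect_setequal(r1$candidates, sim$truth$driver_genes)
})

test_that("driver recovery is reliable at default conditions", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 400 + s)
    sim <- simulate_experiment(cfg, chip = FALSE)
    cr <- prioritize(sim$counts, sim$annotation, sim$design,
                     region = cfg$critical_region, dosage_chromosome = "chr21")
    c(recall = mean(sim$truth$driver_genes %in% cr$candidates),
      precision = if (length(cr$candidates))
        mean(cr$candidates %in% sim$truth$driver_genes) else 1)
  }, numeric(2))
  expect_gte(mean(hits["recall", ]), 0.8)
  expect_gte(mean(hits["precision", ]), 0.6)
})

test_that("recovery improves as count noise shrinks", {
  rec <- function(disp) mean(vapply(1:6, function(s) {
    cfg <- sim_config(seed = 500 + s, dispersion = disp)
    sim <- simulate_experiment(cfg, chip = FALSE)
    cr <- prioritize(sim$counts, sim$annotation, sim$design,
                     region = cfg$critical_region, dosage_chromosome = "chr21")
    mean(sim$truth$driver_genes %in% cr$candidates)
  }, numeric(1)))
  expect_gte(rec(0.002), rec(0.08))
})
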