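# Contrast scaffold, downsampling, negative-binomial testing, BH, and
# proportion shifts.

test_that("the contrast scaffold enumerates the study design", {
  full <- enumerate_contrasts(parsed = TRUE)
  expect_identical(nrow(full), 15L)
  expect_identical(sum(!full$parsed), 4L)   # the four bulk-per-class rows
  bulk <- enumerate_contrasts(parsed = FALSE)
  expect_identical(nrow(bulk), 4L)
  expect_setequal(bulk$name, c("VEHgroup_WTvsHET", "PCBgroup_WTvsHET",
                               "WTgroup_VEHvsPCB", "HETgroup_VEHvsPCB"))
  # per-class restriction, checked against explicit enumeration of the
  # encoded scheme: GABAergic carries the extra mutant-expressing
  # treatment comparison
  gaba <- enumerate_contrasts(neuron_classes = "GABAergic")
  glut <- enumerate_contrasts(neuron_classes = "Glutamatergic")
  expect_identical(nrow(gaba), 8L)
  expect_identical(nrow(glut), 7L)
  expect_setequal(setdiff(sub("_GABA", "", gaba$name),
                          sub("_Glut", "", glut$name)),
                  "HETMUTexpr_PCBvsVEH")
  # sides are disjoint cell selections
  same <- full$a_genotype == full$b_genotype &
    full$a_treatment == full$b_treatment & full$a_allele == full$b_allele
  expect_false(any(same))
  expect_error(enumerate_contrasts(genotypes = c("WT", "HOM")), "genotype")
  expect_error(enumerate_contrasts(treatments = "DOSE"), "treatment")
})

test_that("downsampling equalizes sides reproducibly", {
  ds <- downsample_equal(1:100, 201:260, seed = 4L)
  expect_identical(length(ds$a), 60L)
  expect_identical(length(ds$b), 60L)
  expect_true(all(ds$a %in% 1:100) && all(ds$b %in% 201:260))
  expect_identical(ds, downsample_equal(1:100, 201:260, seed = 4L))
  expect_false(identical(ds$a, downsample_equal(1:100, 201:260, 5L)$a))
  expect_error(downsample_equal(integer(0), 1:5), "empty")
})

test_that("the NB test is symmetric and needs two cells per side", {
  y <- c(3L, 0L, 5L, 2L, 1L, 4L)
  lib <- rep(1000L, 6)
  same <- nb_test_gene(y, y, lib, lib)
  expect_equal(same$log2fc, 0, tolerance = 1e-8)
  set.seed(9)
  for (i in 1:20) {
    a <- rnbinom(30, mu = 5, size = 2); b <- rnbinom(30, mu = 8, size = 2)
    la <- rep(2000, 30); lb <- rep(2000, 30)
    ab <- nb_test_gene(a, b, la, lb)
    ba <- nb_test_gene(b, a, lb, la)
    expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-6)
    expect_equal(ab$p, ba$p, tolerance = 1e-6)
  }
  expect_error(nb_test_gene(1L, c(1L, 2L), 10, c(10, 10)), "2 cells")
  # both sides empty of counts: untestable
  expect_true(is.na(nb_test_gene(c(0L, 0L), c(0L, 0L),
                                 c(10, 10), c(10, 10))$p))
})

test_that("BH adjustment matches the hand-rolled step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  p_na <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p_na)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 2)), "0, 1")
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("planted effects are recovered and null contrasts stay quiet", {
  cfg <- sim_config(
    cells_per_sample = 80L, n_genes = 600L, n_markers_per_type = 5L,
    module_spec = data.frame(size = 20L, cor = 0.5),
    module_trait_effect = NULL,
    deg_spec = list(list(name = "pcb", factor = "treatment", level = "PCB",
                         n_genes = 40L, lfc = 2)),
    seed = 40L)
  tr <- simulate_truth(cfg)
  cnt <- simulate_counts(tr, cfg)
  meta <- cnt$cell_meta
  meta$allele <- tr$allele
  spec <- enumerate_contrasts(parsed = FALSE)
  spec <- spec[spec$name == "HETgroup_VEHvsPCB", ]
  res <- run_contrast(cnt$counts, meta, spec, seed = 2L)
  planted <- cnt$deg_truth$gene
  top <- select_heatmap_genes(res, k = 40L)
  expect_gte(length(intersect(top, planted)) / 40, 0.9)
  # estimated effect size close to the planted value
  expect_lt(abs(median(res$log2fc[match(planted, res$gene)]) - 2), 0.4)
  # a contrast with no planted signal: WT VEH vs PCB has no planted DE
  cfg0 <- sim_config(cells_per_sample = 50L, n_genes = 600L,
                     n_markers_per_type = 5L,
                     module_spec = data.frame(size = 20L, cor = 0.5),
                     module_trait_effect = NULL,
                     deg_spec = list(), seed = 41L)
  tr0 <- simulate_truth(cfg0)
  cnt0 <- simulate_counts(tr0, cfg0)
  meta0 <- cnt0$cell_meta
  meta0$allele <- tr0$allele
  spec0 <- enumerate_contrasts(parsed = FALSE)
  res0 <- run_contrast(cnt0$counts, meta0,
                       spec0[spec0$name == "WTgroup_VEHvsPCB", ], seed = 3L)
  expect_lte(sum(res0$padj <= 0.05, na.rm = TRUE), 3L)
  # k beyond the significant count returns everything significant
  n_sig <- sum(res$padj <= 0.05, na.rm = TRUE)
  expect_identical(length(select_heatmap_genes(res, k = 10 * n_sig)), n_sig)
  expect_warning(select_heatmap_genes(res0[seq_len(5), ], 3), "significant")
})

test_that("parsed contrasts exclude unassigned cells and skip empty
           sides", {
  cfg <- tiny_config(seed = 42L)
  tr <- simulate_truth(cfg)
  cnt <- simulate_counts(tr, cfg)
  meta <- cnt$cell_meta
  meta$allele <- NA_character_  # nothing parsed
  spec <- enumerate_contrasts(parsed = TRUE)
  spec <- spec[spec$parsed, ][1, ]
  expect_message(
    expect_null(run_contrast(cnt$counts, meta, spec)), "skipped")
})

test_that("proportion shifts are tested per type with BH correction", {
  # identical composition in both conditions: nothing approaching
  # significance
  labels <- rep(rep(c("A", "B", "C"), times = c(60, 30, 30)), 2)
  cond <- rep(c("x", "y"), each = 120)
  pt <- proportion_test(labels, cond)
  expect_gte(min(pt$p), 0.5)
  # a type private to one condition at large n is significant
  labels2 <- c(rep("A", 150), rep("B", 150), rep("A", 150), rep("B", 90),
               rep("C", 60))
  cond2 <- rep(c("x", "y"), each = 300)
  pt2 <- proportion_test(labels2, cond2)
  expect_lte(pt2$padj[pt2$cell_type == "C"], 0.05)
  # a single cell type has no composition to shift
  pt3 <- proportion_test(rep("A", 50), rep(c("x", "y"), 25))
  expect_equal(pt3$padj, 1)
  expect_error(proportion_test(rep("A", 4), rep("x", 4)), "2 conditions")
})
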