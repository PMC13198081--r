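# Synthetic-data generator: configuration validation, determinism, and
# recovery of the planted statistical structure.

test_that("configuration validation names the offending field", {
  expect_error(sim_config(xci_ratio = 1.5), "xci_ratio")
  expect_error(sim_config(cells_per_sample = 0), "cells_per_sample")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(n_genes = 100), "n_genes")  # roles don't fit
  expect_error(
    sim_config(deg_spec = list(list(name = "x", factor = "treatment",
                                    level = "DOSE2", n_genes = 5, lfc = 1))),
    "level")
  expect_error(
    sim_config(qc_violation_rates = c(high_genes = 0.01)),
    "high_genes")
})

test_that("truth table has the configured design and is deterministic", {
  cfg <- tiny_config(seed = 5L)
  tr <- simulate_truth(cfg)
  # 2 genotypes x 2 treatments x 4 samples/group = 16 samples
  expect_identical(length(unique(tr$sample_id)), 16L)
  expect_identical(nrow(tr), 16L * cfg$cells_per_sample)
  expect_true(all(table(tr$sample_id) == cfg$cells_per_sample))
  # barcodes unique within each sample
  expect_false(any(duplicated(paste(tr$sample_id, tr$barcode))))
  # mutant allele only in HET cells
  expect_true(all(tr$allele[tr$genotype == "WT"] == "WT"))
  # byte-identical rerun
  expect_identical(tr, simulate_truth(cfg))
  cnt <- simulate_counts(tr, cfg)
  expect_identical(cnt$counts, simulate_counts(tr, cfg)$counts)
})

test_that("a WT-only design expresses only the wild-type allele", {
  cfg <- tiny_config(genotypes = "WT", seed = 2L)
  tr <- simulate_truth(cfg)
  expect_true(all(tr$allele == "WT"))
})

test_that("XCI mosaicism matches the configured ratio", {
  # 4 HET samples x 2500 cells = 10,000 HET cells
  cfg <- sim_config(genotypes = "HET", treatments = "VEH",
                    cells_per_sample = 2500L, n_samples_per_group = 4L,
                    n_genes = 900L, xci_ratio = 0.5, seed = 8L)
  tr <- simulate_truth(cfg)
  expect_identical(nrow(tr), 10000L)
  expect_lt(abs(mean(tr$allele == "MUT") - 0.5), 0.02)
})

test_that("counts conserve library sizes and match the NB family", {
  cfg <- tiny_config(seed = 3L)
  tr <- simulate_truth(cfg)
  cnt <- simulate_counts(tr, cfg)
  # conservation: realized library sizes recorded in the truth table
  expect_identical(as.integer(rowSums(cnt$counts)),
                   as.integer(cnt$truth$library_size))
  expect_identical(cnt$cell_meta$n_umi, as.integer(rowSums(cnt$counts)))

  # alpha = 0 degenerates to Poisson: variance/mean ratio near 1 across
  # background genes of a homogeneous population
  cfg0 <- module_config(n_genes = 500L, cells_per_sample = 60L,
                        module_spec = data.frame(size = 20L, cor = 0.5),
                        nb_dispersion = 0, libsize_lognormal = c(log(2000), 0),
                        seed = 4L)
  tr0 <- simulate_truth(cfg0)
  cnt0 <- simulate_counts(tr0, cfg0)
  bg <- cnt0$gene_meta$gene[cnt0$gene_meta$role == "background"]
  vm <- apply(cnt0$counts[, bg], 2, var) / colMeans(cnt0$counts[, bg])
  vm <- vm[is.finite(vm) & colMeans(cnt0$counts[, bg]) > 0.5]
  expect_lt(abs(mean(vm) - 1), 0.1)
})

test_that("planted log2FC of 1 doubles mean counts at large n", {
  cfg <- sim_config(cells_per_sample = 650L, n_genes = 1000L, seed = 6L)
  tr <- simulate_truth(cfg)
  expect_gte(nrow(tr), 10000L)
  cnt <- simulate_counts(tr, cfg)
  genes <- cnt$deg_truth$gene[cnt$deg_truth$factor == "treatment"]
  pcb <- tr$treatment == "PCB"
  ratio <- colMeans(cnt$counts[pcb, genes]) /
    colMeans(cnt$counts[!pcb, genes])
  expect_lt(abs(mean(ratio) - 2), 0.15)
})

test_that("planted modules show the configured within-block correlation", {
  cfg <- module_config(n_genes = 800L, cells_per_sample = 315L, seed = 9L)
  tr <- simulate_truth(cfg)
  expect_gte(nrow(tr), 5000L)
  cnt <- simulate_counts(tr, cfg)
  norm <- normalize_log(cnt$counts)
  rbar <- vapply(cfg$module_genes, function(mg) {
    cc <- cor(norm[, mg])
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_true(all(rbar >= 0.5 & rbar <= 0.7))
})

test_that("NB dispersion is recoverable from null genes at 5,000 cells", {
  cfg <- module_config(n_genes = 600L, cells_per_sample = 315L,
                       nb_dispersion = 0.3,
                       module_spec = data.frame(size = 20L, cor = 0.5),
                       seed = 10L)
  tr <- simulate_truth(cfg)
  cnt <- simulate_counts(tr, cfg)
  bg <- cnt$gene_meta$gene[cnt$gene_meta$role == "background"]
  lib <- rowSums(cnt$counts)
  ahat <- vapply(bg, function(g) {
    y <- cnt$counts[, g]
    mu <- lib * sum(y) / sum(lib)
    sum((y - mu)^2 - mu) / sum(mu^2)
  }, numeric(1))
  ahat <- ahat[colMeans(cnt$counts[, bg]) > 1]
  expect_lt(abs(mean(ahat) - 0.3) / 0.3, 0.2)
})

test_that("locus reads carry the cell's allele codon before errors", {
  cfg <- tiny_config(read_error_rate = 0, offtarget_rate = 0,
                     truncated_rate = 0, umi_dup_rate = 0, seed = 12L)
  tr <- simulate_truth(cfg)
  ref <- locus_reference()
  rd <- simulate_locus_reads(tr, ref, cfg)
  expect_true(all(rd$on_target))
  expect_identical(rd$true_codon,
                   tr$allele[match(rd$cell_id, tr$cell_id)])
  # with no errors, every read contains the cell's exact allele sequence
  # in one orientation
  wt_seq <- mosaicx:::.allele_sequence(ref, "WT")
  mut_seq <- mosaicx:::.allele_sequence(ref, "MUT")
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  idx <- sample(nrow(rd), 200L)
  hit <- vapply(idx, function(i) {
    target <- if (rd$true_codon[i] == "MUT") mut_seq else wt_seq
    grepl(target, rd$seq2[i], fixed = TRUE) ||
      grepl(target, rc(rd$seq2[i]), fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  # read 1 is barcode + UMI
  expect_identical(rd$seq1, paste0(rd$barcode, rd$umi))
})

test_that("PCR duplicates share barcode and UMI; errors occur at the
           configured rate", {
  cfg <- tiny_config(umi_dup_rate = 1.5, read_error_rate = 0, seed = 13L)
  tr <- simulate_truth(cfg)
  ref <- locus_reference()
  rd <- simulate_locus_reads(tr, ref, cfg)
  key <- paste(rd$barcode, rd$umi)
  expect_gt(sum(duplicated(key)), 0L)
  # duplicates carry the same fragment when error-free
  dup <- key[duplicated(key)][1]
  expect_identical(length(unique(rd$seq2[key == dup])), 1L)

  # substitution rate ~ Poisson(rate x length): pad-free 100-base reads at
  # rate 0.001 average 0.1 mismatches against the clean allele sequence
  cfg2 <- tiny_config(read_error_rate = 0.001, offtarget_rate = 0,
                      truncated_rate = 0, umi_dup_rate = 0,
                      read2_length = 100L, seed = 14L)
  tr2 <- simulate_truth(cfg2)
  rd2 <- simulate_locus_reads(tr2, ref, cfg2)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  clean <- vapply(c("WT", "MUT"), function(a) {
    mosaicx:::.allele_sequence(ref, a)
  }, character(1))
  idx <- seq_len(min(2000L, nrow(rd2)))
  mism <- vapply(idx, function(i) {
    target <- strsplit(clean[[rd2$true_codon[i]]], "")[[1]]
    fwd <- sum(strsplit(rd2$seq2[i], "")[[1]] != target)
    rev <- sum(strsplit(rc(rd2$seq2[i]), "")[[1]] != target)
    min(fwd, rev)
  }, numeric(1))
  expect_lt(abs(mean(mism) - 0.1), 0.05)
})

test_that("gene sets and ortholog maps have the planted structure", {
  cfg <- tiny_config(seed = 15L)
  tr <- simulate_truth(cfg)
  cnt <- simulate_counts(tr, cfg)
  sets <- simulate_genesets(cfg, cnt$deg_truth, n_sets = 20L,
                            n_enriched = 3L, overlap_fraction = 0.5)
  planted <- unique(cnt$deg_truth$gene)
  for (nm in grep("^enriched_", names(sets), value = TRUE)) {
    a <- length(intersect(sets[[nm]], planted))
    expect_identical(a, as.integer(round(0.5 * length(sets[[nm]]))))
  }

  om <- simulate_ortholog_map(cfg)
  # each one2many human gene has exactly one primary target
  o2m <- om$map[om$map$relationship == "one2many", ]
  expect_true(all(tapply(o2m$primary, o2m$human_gene, sum) == 1))
  # unmapped fraction ~ 0.1 of the universe
  cfg2 <- tiny_config(n_genes = 1000L, seed = 16L)
  om2 <- simulate_ortholog_map(cfg2)
  n_unmapped <- sum(om2$classes == "unmapped")
  expect_lt(abs(n_unmapped - 100), 30)
  expect_false(any(toupper(names(om2$classes)[om2$classes == "unmapped"])
                   %in% om2$map$human_gene))
})
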