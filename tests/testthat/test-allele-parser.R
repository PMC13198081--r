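# Allele parser: local alignment, codon classification, UMI collapsing,
# and per-cell allele calls.

ref <- locus_reference()

test_that("alignment handles identity, substitutions, and rejects noise", {
  # exact copy of the reference: identity 1, offset 0
  al <- align_to_locus(ref$sequence, ref)
  expect_equal(al$identity, 1)
  expect_identical(al$ref_start, 0L)
  expect_identical(al$n_columns, 100L)

  # two substitutions: identity 0.98, still accepted at defaults
  s <- ref$sequence
  substr(s, 10, 10) <- if (substr(s, 10, 10) == "A") "C" else "A"
  substr(s, 80, 80) <- if (substr(s, 80, 80) == "G") "T" else "G"
  al2 <- align_to_locus(s, ref)
  expect_false(is.null(al2))
  expect_equal(al2$identity, 0.98)

  # reverse-complement orientation is recovered
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ref$sequence)))
  al3 <- align_to_locus(rc, ref)
  expect_identical(al3$strand, "-")
  expect_equal(al3$identity, 1)

  # random reads never reach 90% identity over 40+ columns
  set.seed(101)
  rejected <- vapply(seq_len(1000), function(i) {
    is.null(align_to_locus(rand_seq(150), ref))
  }, logical(1))
  expect_true(all(rejected))

  expect_error(align_to_locus("ACGTX", ref), "non-ACGTN")
})

test_that("aligner agrees with the dynamic-programming oracle", {
  set.seed(202)
  params <- parser_params(min_identity = 0, min_aligned_length = 1)
  for (i in seq_len(150)) {
    len <- sample(15:60, 1)
    # mix of pure noise and mutated reference fragments
    read <- if (i %% 2 == 0) rand_seq(len) else {
      start <- sample(1:(100 - len + 1), 1)
      frag <- substr(ref$sequence, start, start + len - 1)
      pos <- sample(len, sample(0:3, 1))
      for (p in pos) substr(frag, p, p) <- sample(c("A", "C", "G", "T"), 1)
      frag
    }
    got <- mosaicx:::.sw_align_cpp(read, ref$sequence, 1, -1, -2)
    want <- sw_score_oracle(read, ref$sequence)
    expect_equal(got$score, want, info = paste("read", i))
  }
})

test_that("codon classification reads the three codon bases", {
  wt_read <- substr(ref$sequence, 31, 80)          # covers codon 51-53
  expect_identical(classify_read(align_to_locus(wt_read, ref), ref), "WT")

  mut_seq <- mosaicx:::.allele_sequence(ref, "MUT")
  mut_read <- substr(mut_seq, 31, 80)
  expect_identical(classify_read(align_to_locus(mut_read, ref), ref), "MUT")

  # a third codon is ambiguous
  acg <- paste0(substr(ref$sequence, 1, 50), "ACG",
                substr(ref$sequence, 54, 100))
  expect_identical(classify_read(align_to_locus(acg, ref), ref),
                   "AMBIGUOUS")

  # an alignment that stops short of the codon is ambiguous
  left <- substr(ref$sequence, 1, 45)
  expect_identical(classify_read(align_to_locus(left, ref), ref),
                   "AMBIGUOUS")
})

test_that("UMI collapsing is majority-vote, tie-dropping, idempotent and
           order-invariant", {
  obs <- data.frame(
    barcode = c("B1", "B1", "B1", "B1", "B1", "B2", "B2", "B3"),
    umi = c("U1", "U1", "U2", "U2", "U2", "U3", "U3", "U4"),
    codon_call = c("WT", "WT", "WT", "WT", "MUT", "WT", "MUT", "AMBIGUOUS"),
    stringsAsFactors = FALSE)
  got <- collapse_umis(obs)
  # U1: duplicates collapse; U2: majority WT; U3: tie dropped; U4: no vote
  expect_identical(got$codon_call, c("WT", "WT"))
  expect_identical(got$umi, c("U1", "U2"))
  # idempotent
  expect_identical(collapse_umis(got), got)
  # order-invariant
  set.seed(7)
  expect_identical(collapse_umis(obs[sample(nrow(obs)), ]), got)
})

test_that("cell calls respect evidence and majority thresholds", {
  umis <- data.frame(
    barcode = c(rep("B1", 3), rep("B2", 10), rep("B3", 5)),
    umi = sprintf("U%02d", 1:18),
    codon_call = c(rep("WT", 3),                 # B1: unanimous WT
                   rep(c("WT", "MUT"), 5),       # B2: 5/5 tie
                   rep("MUT", 5)),               # B3: unanimous MUT
    stringsAsFactors = FALSE)
  calls <- call_cells(umis, parser_params(), barcodes = "B4")
  calls <- calls[order(calls$barcode), ]
  expect_identical(calls$call, c("WT", "UNASSIGNED", "MUT", "UNASSIGNED"))
  expect_equal(calls$majority_fraction, c(1, 0.5, 1, NA))
  expect_identical(calls$n_wt_umis, c(3L, 5L, 0L, 0L))
  # 0.79 majority below the 0.8 threshold
  umis2 <- data.frame(barcode = "B5", umi = sprintf("U%02d", 1:100),
                      codon_call = c(rep("WT", 79), rep("MUT", 21)),
                      stringsAsFactors = FALSE)
  expect_identical(call_cells(umis2)$call, "UNASSIGNED")
  umis3 <- umis2
  umis3$codon_call <- c(rep("WT", 80), rep("MUT", 20))
  expect_identical(call_cells(umis3)$call, "WT")
})

test_that("WT cortices yield zero mutant calls; HET calls are accurate", {
  cfg <- sim_config(genotypes = c("WT", "HET"), cells_per_sample = 40L,
                    n_genes = 900L, read_error_rate = 0.001, seed = 30L)
  tr <- simulate_truth(cfg)
  rd <- simulate_locus_reads(tr, locus_reference(), cfg)
  pa <- parse_alleles(rd, ref = locus_reference())
  m <- merge(pa$cells, tr[, c("barcode", "allele", "genotype")],
             by = "barcode")
  expect_identical(sum(m$call == "MUT" & m$genotype == "WT"), 0L)
  # accuracy on HET cells with >= 3 informative UMIs
  het <- m[m$genotype == "HET" & m$n_wt_umis + m$n_mut_umis >= 3, ]
  acc <- mean(het$call == het$allele)
  expect_gte(acc, 0.99)

  # accuracy is monotonically non-decreasing in min_evidence
  accs <- vapply(1:3, function(ev) {
    cl <- call_cells(pa$umis, parser_params(min_evidence = ev))
    mm <- merge(cl, tr[, c("barcode", "allele")], by = "barcode")
    called <- mm[mm$call != "UNASSIGNED", ]
    mean(called$call == called$allele)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("parsing from a FASTQ pair matches the in-memory result", {
  cfg <- sim_config(cells_per_sample = 10L, n_genes = 900L, seed = 31L)
  tr <- simulate_truth(cfg)
  rd <- simulate_locus_reads(tr, locus_reference(), cfg)
  dir <- withr::local_tempdir()
  write_fastq_pair(rd, file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"))
  from_mem <- parse_alleles(rd)
  from_fq <- parse_alleles(r1_path = file.path(dir, "R1.fastq"),
                           r2_path = file.path(dir, "R2.fastq"))
  expect_identical(from_fq$cells, from_mem$cells)
})
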