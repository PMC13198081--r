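# Synthetic-data generator -----------------------------------------------
#
# Emulates the statistical structure of a mosaic-cortex study: a 2 genotype
# (WT / HET) x 2 treatment (VEH / PCB) design with 4 animals per group,
# X-inactivation mosaicism in HET samples (~50:50 wild-type / mutant allele
# expression), 12 cortical cell types, negative-binomial counts with planted
# genotype / treatment / allele differential expression, planted correlated
# co-expression modules, and barcoded 5' locus reads carrying the
# discriminating start codon. Every downstream stage is testable against
# the ground truth this module emits.

# Default cortical cell types and their relative frequencies.
.default_cell_types <- c("Astro", "L2/3 IT", "L4", "L5 IT", "L6 CT", "Lamp5",
                         "Micro", "OPC", "Oligo", "Pvalb", "Sst", "Vip")
.default_type_props <- c(0.10, 0.17, 0.12, 0.12, 0.12, 0.04,
                         0.03, 0.04, 0.08, 0.07, 0.06, 0.05)

# Broad neuron classes used by the contrast design.
.default_class_map <- c("Astro" = "Non-neuronal", "L2/3 IT" = "Glutamatergic",
                        "L4" = "Glutamatergic", "L5 IT" = "Glutamatergic",
                        "L6 CT" = "Glutamatergic", "Lamp5" = "GABAergic",
                        "Micro" = "Non-neuronal", "OPC" = "Non-neuronal",
                        "Oligo" = "Non-neuronal", "Pvalb" = "GABAergic",
                        "Sst" = "GABAergic", "Vip" = "GABAergic")

# Synthetic 100-base locus reference (NOT a real genomic sequence): random
# background with the wild-type start codon planted at 0-based offset 50.
.synthetic_locus_seq <- paste0(
  "GTCCAGTTAAGCGTGACCTCACGTTAGGATCCAATTCGGAGCTTAACGGT",  # 50 bp upstream
  "ATG",                                                 # start codon
  "CATCGGATTGACCTTAACGTGCAGGCTATCCGAAGTTCACGGATCCA")     # 47 bp downstream

#' Locus reference for allele parsing
#'
#' A 100-base reference spanning 50 bases upstream of the start codon, the
#' codon itself, and the remaining downstream bases. The default sequence is
#' synthetic (random background with the codon planted at offset 50); supply
#' `sequence` to use a real locus.
#'
#' @param sequence 100-base nucleotide string, or `NULL` for the synthetic
#'   default.
#' @param codon_offset 0-based index of the start codon (default 50).
#' @param wt_codon,mut_codon the two discriminating codons (defaults
#'   "ATG" wild type, "TTG" mutant).
#' @return a list of class `locus_reference`.
#' @export
locus_reference <- function(sequence = NULL, codon_offset = 50L,
                            wt_codon = "ATG", mut_codon = "TTG") {
  if (is.null(sequence)) sequence <- .synthetic_locus_seq
  sequence <- toupper(sequence)
  if (nchar(sequence) != 100L) {
    stop("locus reference must be exactly 100 bases", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("locus reference contains non-ACGTN characters", call. = FALSE)
  }
  .check_scalar(codon_offset, "codon_offset", 0, nchar(sequence) - 3,
                integer = TRUE)
  if (identical(wt_codon, mut_codon)) {
    stop("wt_codon and mut_codon must differ", call. = FALSE)
  }
  structure(list(sequence = sequence, codon_offset = as.integer(codon_offset),
                 wt_codon = wt_codon, mut_codon = mut_codon),
            class = "locus_reference")
}

# Reference sequence carrying a given allele's codon.
.allele_sequence <- function(ref, allele) {
  codon <- if (allele == "MUT") ref$mut_codon else ref$wt_codon
  paste0(substr(ref$sequence, 1L, ref$codon_offset),
         codon,
         substr(ref$sequence, ref$codon_offset + 4L, nchar(ref$sequence)))
}

#' Simulation configuration
#'
#' Builds and validates the configuration driving all `simulate_*`
#' generators. Defaults encode the emulated study conditions: 4 samples per
#' genotype-by-treatment group (16 total), 12 cortical cell types, a 50:50
#' X-inactivation ratio in HET samples, negative-binomial counts with
#' dispersion `nb_dispersion`, planted treatment / genotype / allele
#' differential expression, and 7 planted co-expression modules of 50 genes
#' at within-module correlation 0.6.
#'
#' Gene roles are laid out deterministically: mitochondrial genes first,
#' then per-type markers, then module genes, then planted DEGs, then
#' background. Module genes are disjoint from DEG genes so the two truth
#' tables stay independent.
#'
#' @param n_samples_per_group samples per genotype-by-treatment group.
#' @param genotypes,treatments factor levels of the design.
#' @param n_cell_types number of cell types (12 and 3 have named presets).
#' @param cell_types,type_proportions optional explicit types/frequencies.
#' @param cells_per_sample cells simulated per sample.
#' @param xci_ratio fraction of HET cells expressing the mutant allele.
#' @param n_genes total genes (must cover all planted roles).
#' @param n_mito_genes genes flagged mitochondrial.
#' @param n_markers_per_type,marker_log2fc marker planting per cell type.
#' @param deg_spec list of planted DE effects, each
#'   `list(name, factor, level, n_genes, lfc)` (genes auto-assigned) or with
#'   explicit `genes`. `factor` is one of "treatment", "genotype", "allele";
#'   cells at `level` have the listed genes shifted by `lfc` log2 units.
#' @param module_spec data.frame with columns `size` and `cor`: planted
#'   co-expression blocks and their within-block correlation.
#' @param module_trait_effect optional `list(module, factor, level, delta)`:
#'   shift of the latent module activity in cells at `level`.
#' @param nb_dispersion per-gene overdispersion alpha (variance
#'   `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param libsize_lognormal `c(meanlog, sdlog)` of the library-size
#'   distribution.
#' @param mito_beta `c(shape1, shape2)` of the per-cell mitochondrial
#'   fraction distribution.
#' @param qc_violation_rates named rates of planted QC-violating cells over
#'   classes `high_mito`, `low_umi`, `high_umi`, `low_genes`, `high_genes`
#'   (`high_genes` requires `n_genes > 5625`).
#' @param mean_locus_umis mean locus molecules captured per cell.
#' @param umi_dup_rate expected PCR duplicate reads per molecule.
#' @param read_error_rate per-base substitution probability on the cDNA read.
#' @param offtarget_rate fraction of locus molecules that are random
#'   off-target sequence.
#' @param truncated_rate fraction of on-target molecules carrying only a
#'   partial locus fragment.
#' @param read2_length,barcode_length,umi_length read geometry (16-base
#'   barcode + 10-base UMI on read 1; 150-base cDNA read 2 by default).
#' @param gene_names optional explicit gene identifiers.
#' @param seed integer RNG seed; all generators derive their streams from it.
#' @return a validated list of class `mosaicx_sim_config`.
#' @export
sim_config <- function(n_samples_per_group = 4L,
                       genotypes = c("WT", "HET"),
                       treatments = c("VEH", "PCB"),
                       n_cell_types = 12L,
                       cell_types = NULL,
                       type_proportions = NULL,
                       cells_per_sample = 250L,
                       xci_ratio = 0.5,
                       n_genes = 2000L,
                       n_mito_genes = 13L,
                       n_markers_per_type = 20L,
                       marker_log2fc = 2,
                       deg_spec = NULL,
                       module_spec = NULL,
                       module_trait_effect = list(module = 1L,
                                                  factor = "treatment",
                                                  level = "PCB", delta = 1),
                       nb_dispersion = 0.3,
                       libsize_lognormal = c(meanlog = log(2500), sdlog = 0.35),
                       mito_beta = c(2, 78),
                       qc_violation_rates = c(high_mito = 0.005,
                                              low_umi = 0.005,
                                              high_umi = 0.005,
                                              low_genes = 0.005,
                                              high_genes = 0),
                       mean_locus_umis = 4,
                       umi_dup_rate = 0.5,
                       read_error_rate = 0.001,
                       offtarget_rate = 0.1,
                       truncated_rate = 0.15,
                       read2_length = 150L,
                       barcode_length = 16L,
                       umi_length = 10L,
                       gene_names = NULL,
                       seed = 1L) {
  .check_scalar(n_samples_per_group, "n_samples_per_group", 1, Inf, TRUE)
  .check_scalar(n_cell_types, "n_cell_types", 1, Inf, TRUE)
  .check_scalar(cells_per_sample, "cells_per_sample", 1, Inf, TRUE)
  .check_scalar(xci_ratio, "xci_ratio", 0, 1)
  .check_scalar(n_genes, "n_genes", 1, Inf, TRUE)
  .check_scalar(n_mito_genes, "n_mito_genes", 0, n_genes, TRUE)
  .check_scalar(nb_dispersion, "nb_dispersion", 0, Inf)
  .check_scalar(read_error_rate, "read_error_rate", 0, 1)
  .check_scalar(umi_dup_rate, "umi_dup_rate", 0, Inf)
  .check_scalar(offtarget_rate, "offtarget_rate", 0, 1)
  .check_scalar(truncated_rate, "truncated_rate", 0, 1)
  .check_scalar(mean_locus_umis, "mean_locus_umis", 0, Inf)
  .check_scalar(seed, "seed", -2^31, 2^31 - 1, TRUE)
  if (any(qc_violation_rates < 0) || sum(qc_violation_rates) > 1) {
    stop("configuration error: field 'qc_violation_rates' must be ",
         "non-negative with sum <= 1", call. = FALSE)
  }
  qvr <- c(high_mito = 0, low_umi = 0, high_umi = 0, low_genes = 0,
           high_genes = 0)
  unknown <- setdiff(names(qc_violation_rates), names(qvr))
  if (length(unknown)) {
    stop("configuration error: field 'qc_violation_rates' has unknown ",
         "class(es): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  qvr[names(qc_violation_rates)] <- qc_violation_rates
  if (qvr[["high_genes"]] > 0 && n_genes <= 5625L) {
    stop("configuration error: field 'qc_violation_rates' plants ",
         "'high_genes' cells but n_genes <= 5625", call. = FALSE)
  }

  if (is.null(cell_types)) {
    if (n_cell_types == 12L) {
      cell_types <- .default_cell_types
      if (is.null(type_proportions)) type_proportions <- .default_type_props
    } else if (n_cell_types == 3L) {
      cell_types <- c("GABAergic", "Glutamatergic", "Non-neuronal")
    } else {
      cell_types <- sprintf("T%02d", seq_len(n_cell_types))
    }
  }
  if (length(cell_types) != n_cell_types) {
    stop("configuration error: field 'cell_types' length differs from ",
         "'n_cell_types'", call. = FALSE)
  }
  if (is.null(type_proportions)) {
    type_proportions <- rep(1 / n_cell_types, n_cell_types)
  }
  if (length(type_proportions) != n_cell_types ||
      any(type_proportions <= 0)) {
    stop("configuration error: field 'type_proportions' must be positive ",
         "and match 'n_cell_types'", call. = FALSE)
  }
  type_proportions <- type_proportions / sum(type_proportions)

  # Gene universe and deterministic role layout.
  if (is.null(gene_names)) {
    gene_names <- sprintf("Gene%05d", seq_len(n_genes))
    if (n_mito_genes > 0) {
      gene_names[seq_len(n_mito_genes)] <- sprintf("mt-G%02d",
                                                   seq_len(n_mito_genes))
    }
  }
  if (length(gene_names) != n_genes || anyDuplicated(gene_names)) {
    stop("configuration error: field 'gene_names' must be ", n_genes,
         " unique identifiers", call. = FALSE)
  }
  cursor <- n_mito_genes
  take <- function(k) {
    if (cursor + k > n_genes) {
      stop("configuration error: field 'n_genes' too small for the ",
           "planted roles", call. = FALSE)
    }
    out <- gene_names[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  marker_genes <- stats::setNames(
    lapply(seq_len(n_cell_types), function(i) take(n_markers_per_type)),
    cell_types)

  if (is.null(module_spec)) {
    module_spec <- data.frame(size = rep(50L, 7L), cor = rep(0.6, 7L))
  }
  if (!all(c("size", "cor") %in% names(module_spec))) {
    stop("configuration error: field 'module_spec' needs columns ",
         "'size' and 'cor'", call. = FALSE)
  }
  if (any(module_spec$cor < 0 | module_spec$cor >= 1)) {
    stop("configuration error: field 'module_spec' correlations must be ",
         "in [0, 1)", call. = FALSE)
  }
  module_spec$module <- sprintf("M%d", seq_len(nrow(module_spec)))
  module_genes <- stats::setNames(
    lapply(module_spec$size, take), module_spec$module)
  if (anyDuplicated(unlist(module_genes))) {
    stop("configuration error: overlapping module gene sets", call. = FALSE)
  }

  valid_levels <- list(treatment = treatments, genotype = genotypes,
                       allele = c("WT", "MUT"))
  if (is.null(deg_spec)) {
    deg_spec <- list(
      list(name = "pcb_response", factor = "treatment",
           level = treatments[min(2L, length(treatments))],
           n_genes = 100L, lfc = 1),
      list(name = "genotype_response", factor = "genotype",
           level = genotypes[min(2L, length(genotypes))],
           n_genes = 100L, lfc = 1),
      list(name = "allele_response", factor = "allele", level = "MUT",
           n_genes = 50L, lfc = 1))
    # degenerate designs (single level) drop the corresponding effect
    deg_spec <- Filter(function(e) {
      e$level %in% valid_levels[[e$factor]] &&
        (e$factor != "allele" || "HET" %in% genotypes)
    }, deg_spec)
  }
  deg_spec <- lapply(deg_spec, function(e) {
    if (is.null(e$factor) || !e$factor %in% names(valid_levels)) {
      stop("configuration error: field 'deg_spec' factor must be one of ",
           paste(names(valid_levels), collapse = ", "), call. = FALSE)
    }
    if (!e$level %in% valid_levels[[e$factor]]) {
      stop("configuration error: field 'deg_spec' level '", e$level,
           "' not a level of '", e$factor, "'", call. = FALSE)
    }
    if (is.null(e$genes)) e$genes <- take(e$n_genes)
    if (!all(e$genes %in% gene_names)) {
      stop("configuration error: field 'deg_spec' references unknown genes",
           call. = FALSE)
    }
    e$n_genes <- length(e$genes)
    e
  })

  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    genotypes = genotypes, treatments = treatments,
    n_cell_types = as.integer(n_cell_types), cell_types = cell_types,
    type_proportions = type_proportions,
    cells_per_sample = as.integer(cells_per_sample),
    xci_ratio = xci_ratio, n_genes = as.integer(n_genes),
    n_mito_genes = as.integer(n_mito_genes), gene_names = gene_names,
    marker_genes = marker_genes, marker_log2fc = marker_log2fc,
    module_spec = module_spec, module_genes = module_genes,
    module_trait_effect = module_trait_effect,
    deg_spec = deg_spec, nb_dispersion = nb_dispersion,
    libsize_lognormal = libsize_lognormal, mito_beta = mito_beta,
    qc_violation_rates = qvr, mean_locus_umis = mean_locus_umis,
    umi_dup_rate = umi_dup_rate, read_error_rate = read_error_rate,
    offtarget_rate = offtarget_rate, truncated_rate = truncated_rate,
    read2_length = as.integer(read2_length),
    barcode_length = as.integer(barcode_length),
    umi_length = as.integer(umi_length),
    seed = as.integer(seed)), class = "mosaicx_sim_config")
}

#' Human-like simulation preset
#'
#' Convenience wrapper around [sim_config()] emulating a human cortex
#' validation cohort: three broad cell classes (GABAergic, glutamatergic,
#' non-neuronal), a PCB-exposure label instead of a genotype contrast, and
#' upper-case gene symbols so ortholog mapping is exercised.
#'
#' @param mouse_genes mouse gene identifiers whose upper-cased forms become
#'   the human symbols (defaults to the standard synthetic universe).
#' @param ... overrides passed to [sim_config()].
#' @return a `mosaicx_sim_config`.
#' @export
human_sim_config <- function(mouse_genes = NULL, ...) {
  args <- list(...)
  if (is.null(args$n_genes)) args$n_genes <- 2000L
  if (is.null(mouse_genes)) {
    mouse_genes <- sprintf("Gene%05d", seq_len(args$n_genes))
    nm <- if (is.null(args$n_mito_genes)) 13L else args$n_mito_genes
    if (nm > 0) mouse_genes[seq_len(nm)] <- sprintf("mt-G%02d", seq_len(nm))
  }
  defaults <- list(genotypes = "RTT", treatments = c("CTRL", "PCB"),
                   n_cell_types = 3L, xci_ratio = 0,
                   cells_per_sample = 150L,
                   module_spec = data.frame(size = rep(50L, 3L),
                                            cor = rep(0.6, 3L)),
                   module_trait_effect = NULL,
                   gene_names = toupper(mouse_genes), seed = 99L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Random DNA strings, vectorized (all the same length).
.rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate the per-cell ground truth table
#'
#' One row per cell: barcode (unique within sample), sample, genotype,
#' treatment, cell type, expressed allele (mutant only in HET samples, with
#' probability `xci_ratio`), target library size, per-cell mitochondrial
#' fraction, any planted QC-violation class, and the latent per-module
#' activity used to plant co-expression blocks.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `mosaicx_truth`; module loadings in columns
#'   `M1`, `M2`, ...
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "mosaicx_sim_config"))
  set.seed(config$seed)
  groups <- expand.grid(genotype = config$genotypes,
                        treatment = config$treatments,
                        stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    data.frame(sample_id = sprintf("%s_%s_%d", groups$genotype[g],
                                   groups$treatment[g],
                                   seq_len(config$n_samples_per_group)),
               genotype = groups$genotype[g],
               treatment = groups$treatment[g],
               stringsAsFactors = FALSE)
  }))

  n_cells <- nrow(samples) * config$cells_per_sample
  idx <- rep(seq_len(nrow(samples)), each = config$cells_per_sample)
  truth <- samples[idx, , drop = FALSE]
  rownames(truth) <- NULL

  # barcodes unique within each sample
  bc <- .rand_dna(n_cells, config$barcode_length)
  key <- paste(truth$sample_id, bc)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    bc[dup] <- .rand_dna(sum(dup), config$barcode_length)
    key <- paste(truth$sample_id, bc)
  }
  truth$barcode <- bc
  truth$cell_id <- paste(truth$sample_id, truth$barcode, sep = ":")

  truth$cell_type <- sample(config$cell_types, n_cells, replace = TRUE,
                            prob = config$type_proportions)
  truth$allele <- ifelse(
    truth$genotype == "HET" & rbinom(n_cells, 1L, config$xci_ratio) == 1L,
    "MUT", "WT")
  truth$library_size <- pmax(
    50, round(rlnorm(n_cells, config$libsize_lognormal[[1]],
                     config$libsize_lognormal[[2]])))
  truth$mito_fraction <- rbeta(n_cells, config$mito_beta[[1]],
                               config$mito_beta[[2]])

  qvr <- config$qc_violation_rates
  truth$qc_class <- sample(c("none", names(qvr)), n_cells, replace = TRUE,
                           prob = c(1 - sum(qvr), qvr))
  hm <- truth$qc_class == "high_mito"
  truth$mito_fraction[hm] <- runif(sum(hm), 0.09, 0.25)
  lu <- truth$qc_class == "low_umi"
  truth$library_size[lu] <- sample(50:150, sum(lu), replace = TRUE)
  hu <- truth$qc_class == "high_umi"
  truth$library_size[hu] <- sample(17000:25000, sum(hu), replace = TRUE)
  lg <- truth$qc_class == "low_genes"
  truth$library_size[lg] <- sample(400:600, sum(lg), replace = TRUE)

  # latent module activities (standard normal, plus any planted trait shift)
  n_mod <- nrow(config$module_spec)
  if (n_mod > 0) {
    load <- matrix(rnorm(n_cells * n_mod), n_cells, n_mod,
                   dimnames = list(NULL, config$module_spec$module))
    eff <- config$module_trait_effect
    if (!is.null(eff)) {
      hit <- truth[[eff$factor]] == eff$level
      load[hit, eff$module] <- load[hit, eff$module] + eff$delta
    }
    truth <- cbind(truth, load)
  }
  truth <- truth[, c("cell_id", "barcode", "sample_id", "genotype",
                     "treatment", "cell_type", "allele", "library_size",
                     "mito_fraction", "qc_class",
                     if (n_mod > 0) config$module_spec$module)]
  class(truth) <- c("mosaicx_truth", "data.frame")
  truth
}

#' Simulate a cell-by-gene count matrix with planted structure
#'
#' Counts follow a negative binomial with mean `library_size x relative
#' abundance` and variance `mu + alpha mu^2`. Cell-type markers, planted
#' DEGs, and the per-cell mitochondrial fraction enter through the relative
#' abundances; planted co-expression modules are drawn through a Gaussian
#' copula on the cell's latent module activity so that within-module
#' expression shows the configured correlation while keeping the negative
#' binomial marginals.
#'
#' @param truth a [simulate_truth()] table.
#' @param config the same [sim_config()].
#' @return list with `counts` (cells x genes), `cell_meta` (QC metrics,
#'   labels), `gene_meta` (mito flag, role, module), `truth` (input truth
#'   with `library_size` replaced by the realized per-cell UMI total),
#'   `deg_truth` and `module_truth` planted-effect tables, and `signatures`
#'   (the generating per-type mean log-normalized profiles).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "mosaicx_sim_config"))
  set.seed(config$seed + 1L)
  n_cells <- nrow(truth)
  genes <- config$gene_names
  n_genes <- config$n_genes

  # baseline relative abundances
  q_base <- rgamma(n_genes, shape = 0.4, rate = 1) + 1e-4
  names(q_base) <- genes
  mod_genes_all <- unlist(config$module_genes, use.names = FALSE)
  # module genes get a moderate, well-measured abundance so counting noise
  # does not swamp the planted correlation
  q_base[mod_genes_all] <- mean(q_base) * 2.5
  mito <- genes[seq_len(config$n_mito_genes)]
  if (length(mito)) q_base[mito] <- mean(q_base)

  Q <- matrix(rep(q_base, each = n_cells), n_cells, n_genes,
              dimnames = list(truth$cell_id, genes))

  # cell-type marker shifts
  for (ty in names(config$marker_genes)) {
    rows <- truth$cell_type == ty
    if (any(rows)) {
      Q[rows, config$marker_genes[[ty]]] <-
        Q[rows, config$marker_genes[[ty]]] * 2^config$marker_log2fc
    }
  }
  # planted DE shifts
  for (e in config$deg_spec) {
    rows <- truth[[e$factor]] == e$level
    if (any(rows)) Q[rows, e$genes] <- Q[rows, e$genes] * 2^e$lfc
  }
  # low-genes QC violators express only a small fixed gene subset
  lg <- which(truth$qc_class == "low_genes")
  if (length(lg)) {
    support <- sample(genes, 150L)
    Q[lg, setdiff(genes, support)] <- 0
  }
  # per-cell mitochondrial fraction
  if (length(mito)) {
    msum <- rowSums(Q[, mito, drop = FALSE])
    osum <- rowSums(Q[, setdiff(genes, mito), drop = FALSE])
    f <- truth$mito_fraction
    Q[, mito] <- Q[, mito, drop = FALSE] * ifelse(msum > 0, f / msum, 0)
    Q[, setdiff(genes, mito)] <-
      Q[, setdiff(genes, mito), drop = FALSE] * (1 - f) / osum
  }
  Q <- Q / rowSums(Q)
  mu <- Q * truth$library_size

  alpha <- config$nb_dispersion
  counts <- matrix(0L, n_cells, n_genes, dimnames = dimnames(mu))
  plain <- setdiff(genes, mod_genes_all)
  if (alpha > 0) {
    counts[, plain] <- rnbinom(n_cells * length(plain),
                               size = 1 / alpha, mu = mu[, plain])
  } else {
    counts[, plain] <- rpois(n_cells * length(plain), mu[, plain])
  }
  # module blocks: Gaussian copula on the latent activity
  for (i in seq_len(nrow(config$module_spec))) {
    mg <- config$module_genes[[i]]
    rho <- config$module_spec$cor[i]
    f <- truth[[config$module_spec$module[i]]]
    f <- (f - mean(f)) / stats::sd(f)  # unit-variance latent
    z <- sqrt(rho) * matrix(f, n_cells, length(mg)) +
      sqrt(1 - rho) * matrix(rnorm(n_cells * length(mg)), n_cells)
    u <- pnorm(z)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    if (alpha > 0) {
      counts[, mg] <- qnbinom(u, size = 1 / alpha, mu = mu[, mg])
    } else {
      counts[, mg] <- qpois(u, mu[, mg])
    }
  }
  storage.mode(counts) <- "integer"

  role <- rep("background", n_genes)
  names(role) <- genes
  role[unlist(config$marker_genes, use.names = FALSE)] <- "marker"
  role[mod_genes_all] <- "module"
  deg_truth <- do.call(rbind, lapply(config$deg_spec, function(e) {
    data.frame(gene = e$genes, effect = e$name, factor = e$factor,
               level = e$level, lfc = e$lfc, stringsAsFactors = FALSE)
  }))
  if (!is.null(deg_truth)) role[deg_truth$gene] <- "deg"
  if (length(mito)) role[mito] <- "mito"
  module_of <- rep(NA_character_, n_genes)
  names(module_of) <- genes
  for (m in names(config$module_genes)) {
    module_of[config$module_genes[[m]]] <- m
  }
  gene_meta <- data.frame(gene = genes, is_mito = genes %in% mito,
                          role = unname(role), module = unname(module_of),
                          stringsAsFactors = FALSE)
  module_truth <- data.frame(
    gene = mod_genes_all,
    module = rep(names(config$module_genes),
                 vapply(config$module_genes, length, 1L)),
    stringsAsFactors = FALSE)

  n_umi <- as.integer(rowSums(counts))
  n_expr <- as.integer(rowSums(counts > 0))
  mito_frac <- if (length(mito)) {
    rowSums(counts[, mito, drop = FALSE]) / pmax(n_umi, 1L)
  } else rep(0, n_cells)
  cell_meta <- data.frame(cell_id = truth$cell_id, barcode = truth$barcode,
                          sample_id = truth$sample_id,
                          genotype = truth$genotype,
                          treatment = truth$treatment,
                          cell_type = truth$cell_type,
                          allele = truth$allele,
                          n_umi = n_umi, n_genes = n_expr,
                          mito_fraction = mito_frac,
                          stringsAsFactors = FALSE)
  truth$library_size <- n_umi  # realized totals
  list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
       truth = truth, deg_truth = deg_truth, module_truth = module_truth)
}

#' Simulate barcoded paired 5' locus reads
#'
#' Each cell captures a Poisson number of locus molecules; each molecule
#' carries a unique UMI and yields one read pair plus a Poisson number of
#' PCR duplicates sharing the (barcode, UMI). Read 1 is barcode + UMI;
#' read 2 is a 150-base cDNA read containing the full locus, a truncated
#' fragment of it, or random off-target sequence, in either orientation,
#' with per-base substitution errors applied after the cell's allele codon
#' is planted.
#'
#' @param truth a [simulate_truth()] table.
#' @param ref a [locus_reference()].
#' @param config the same [sim_config()].
#' @return data.frame with `read_id`, `cell_id`, `barcode`, `umi`, `seq1`,
#'   `seq2`, `on_target`, and the pre-error `true_codon` for on-target
#'   molecules covering the codon.
#' @export
simulate_locus_reads <- function(truth, ref, config) {
  stopifnot(inherits(config, "mosaicx_sim_config"),
            inherits(ref, "locus_reference"))
  set.seed(config$seed + 2L)
  n_mol_per_cell <- rpois(nrow(truth), config$mean_locus_umis)
  cell_idx <- rep(seq_len(nrow(truth)), n_mol_per_cell)
  n_mol <- length(cell_idx)
  if (n_mol == 0L) {
    return(data.frame(read_id = character(0), cell_id = character(0),
                      barcode = character(0), umi = character(0),
                      seq1 = character(0), seq2 = character(0),
                      on_target = logical(0), true_codon = character(0),
                      stringsAsFactors = FALSE))
  }
  umi <- .rand_dna(n_mol, config$umi_length)
  on_target <- runif(n_mol) >= config$offtarget_rate
  L2 <- config$read2_length
  reflen <- nchar(ref$sequence)

  allele_seq <- vapply(c(WT = "WT", MUT = "MUT"),
                       function(a) .allele_sequence(ref, a), character(1))
  frag <- character(n_mol)
  covers <- logical(n_mol)
  full <- on_target & runif(n_mol) >= config$truncated_rate
  part <- on_target & !full
  frag[full] <- allele_seq[truth$allele[cell_idx[full]]]
  covers[full] <- TRUE
  if (any(part)) {
    fl <- sample(40:80, sum(part), replace = TRUE)
    fs <- vapply(fl, function(l) sample.int(reflen - l + 1L, 1L), 1L)
    frag[part] <- substr(allele_seq[truth$allele[cell_idx[part]]],
                         fs, fs + fl - 1L)
    covers[part] <- fs <= ref$codon_offset + 1L &
      fs + fl - 1L >= ref$codon_offset + 3L
  }

  # embed fragments in a random background to full read length
  pad_total <- L2 - nchar(frag)
  pad_total[!on_target] <- L2
  frag[!on_target] <- ""
  pre_len <- vapply(pad_total, function(p) sample.int(p + 1L, 1L) - 1L, 1L)
  bg <- .rand_dna(n_mol, L2)
  seq2 <- paste0(substr(bg, 1L, pre_len), frag,
                 substr(bg, pre_len + 1L, pad_total))

  # random orientation
  flip <- runif(n_mol) < 0.5
  seq2[flip] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq2[flip])))

  # expand molecules to reads (1 + Poisson duplicates), then apply errors
  n_reads <- 1L + rpois(n_mol, config$umi_dup_rate)
  mol_idx <- rep(seq_len(n_mol), n_reads)
  seq2 <- seq2[mol_idx]
  if (config$read_error_rate > 0) {
    n_err <- rbinom(length(seq2), L2, config$read_error_rate)
    for (k in which(n_err > 0)) {
      pos <- sample.int(L2, n_err[k])
      s <- strsplit(seq2[k], "")[[1]]
      s[pos] <- vapply(s[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
      seq2[k] <- paste(s, collapse = "")
    }
  }
  ci <- cell_idx[mol_idx]
  data.frame(
    read_id = sprintf("read%07d", seq_along(mol_idx)),
    cell_id = truth$cell_id[ci],
    barcode = truth$barcode[ci],
    umi = umi[mol_idx],
    seq1 = paste0(truth$barcode[ci], umi[mol_idx]),
    seq2 = seq2,
    on_target = on_target[mol_idx],
    true_codon = ifelse(on_target[mol_idx] & covers[mol_idx],
                        truth$allele[ci], NA_character_),
    stringsAsFactors = FALSE)
}

#' Simulate a gene-set collection (GMT stand-in)
#'
#' Random gene sets plus "enriched" sets built to overlap the planted DEGs
#' by a configured fraction, so downstream over-representation statistics
#' have a recoverable truth.
#'
#' @param config a [sim_config()].
#' @param deg_truth planted-DEG table from [simulate_counts()] (optional;
#'   when `NULL`, the configured planted genes are used directly).
#' @param n_sets number of random background sets.
#' @param size_range inclusive range of random set sizes.
#' @param n_enriched number of DEG-overlapping sets.
#' @param overlap_fraction fraction of each enriched set drawn from the
#'   planted DEGs.
#' @return named list of gene sets; enriched sets are named
#'   `"enriched_<i>"`.
#' @export
simulate_genesets <- function(config, deg_truth = NULL, n_sets = 50L,
                              size_range = c(20L, 150L), n_enriched = 5L,
                              overlap_fraction = 0.5) {
  stopifnot(inherits(config, "mosaicx_sim_config"))
  set.seed(config$seed + 3L)
  genes <- config$gene_names
  planted <- if (is.null(deg_truth)) {
    unique(unlist(lapply(config$deg_spec, `[[`, "genes")))
  } else unique(deg_truth$gene)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(size_range[1]:size_range[2], 1L))
  })
  names(sets) <- sprintf("pathway_%03d", seq_len(n_sets))
  if (n_enriched > 0L && length(planted)) {
    for (i in seq_len(n_enriched)) {
      sz <- sample(size_range[1]:size_range[2], 1L)
      k <- min(round(overlap_fraction * sz), length(planted))
      sets[[sprintf("enriched_%d", i)]] <-
        c(sample(planted, k), sample(setdiff(genes, planted), sz - k))
    }
  }
  sets
}

#' Simulate a cross-species ortholog map
#'
#' Human symbols are the upper-cased mouse identifiers. Mouse genes are
#' partitioned into one-to-one, one-to-many (two targets, exactly one
#' flagged primary), many-to-one (two human genes sharing a mouse target),
#' and unmapped classes in the configured proportions.
#'
#' @param config a [sim_config()] supplying the mouse gene universe.
#' @param props named proportions over `one2one`, `one2many`, `many2one`,
#'   `unmapped` (normalized internally).
#' @return list with `map` (data.frame: `human_gene`, `mouse_gene`,
#'   `relationship`, `primary`) and `classes` (per-human-gene class,
#'   including unmapped genes absent from `map`).
#' @export
simulate_ortholog_map <- function(config,
                                  props = c(one2one = 0.7, one2many = 0.1,
                                            many2one = 0.1, unmapped = 0.1)) {
  stopifnot(inherits(config, "mosaicx_sim_config"))
  set.seed(config$seed + 4L)
  props <- props / sum(props)
  mouse <- config$gene_names
  human <- toupper(mouse)
  cls <- sample(names(props), length(mouse), replace = TRUE, prob = props)
  rows <- list()
  for (i in seq_along(mouse)) {
    if (cls[i] == "one2one") {
      rows[[length(rows) + 1L]] <- data.frame(
        human_gene = human[i], mouse_gene = mouse[i],
        relationship = "one2one", primary = TRUE,
        stringsAsFactors = FALSE)
    } else if (cls[i] == "one2many") {
      alt <- paste0(mouse[i], "-ps")  # paralogous secondary target
      rows[[length(rows) + 1L]] <- data.frame(
        human_gene = rep(human[i], 2L),
        mouse_gene = c(mouse[i], alt),
        relationship = "one2many", primary = c(TRUE, FALSE),
        stringsAsFactors = FALSE)
    } else if (cls[i] == "many2one") {
      alt <- paste0(human[i], "B")  # second human gene, same mouse target
      rows[[length(rows) + 1L]] <- data.frame(
        human_gene = c(human[i], alt),
        mouse_gene = rep(mouse[i], 2L),
        relationship = "many2one", primary = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  classes <- stats::setNames(cls, human)
  list(map = map, classes = classes)
}
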