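# End-to-end orchestrator --------------------------------------------------
#
# simulate -> parse -> qc -> annotate -> deg -> enrich -> modules ->
# cross-species, with every stage's seed, inputs, and outputs captured in
# a run manifest. All outputs are plain TSV/MTX/FASTQ/GMT files so a rerun
# with the same configuration is byte-identical.

# Defaults for the demo run; any field can be overridden from YAML.
.default_run_config <- function() {
  list(seed = 1L,
       sim = list(cells_per_sample = 50L, n_genes = 600L,
                  module_spec = data.frame(size = rep(30L, 3L),
                                           cor = rep(0.6, 3L)),
                  mean_locus_umis = 3),
       parser = list(),
       qc = list(),
       network = list(pooling_size = 10L, min_module_size = 10L),
       deg = list(fdr = 0.05, min_cells = 10L),
       human = list(cells_per_sample = 40L, n_genes = 600L),
       enrich = list())
}

.load_run_config <- function(config) {
  cfg <- .default_run_config()
  config_hash <- NA_character_
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  # module_spec is table-valued: replaced wholesale, never merged
  # element-wise (modifyList would recurse into its columns)
  ms <- cfg$sim$module_spec
  cfg$sim$module_spec <- NULL
  if (!is.null(config)) {
    if (!is.null(config$sim$module_spec)) ms <- config$sim$module_spec
    config$sim$module_spec <- NULL
    cfg <- utils::modifyList(cfg, config)
  }
  if (!is.null(ms) && !is.data.frame(ms)) ms <- as.data.frame(ms)
  cfg$sim$module_spec <- ms
  cfg$config_hash <- config_hash
  cfg
}

#' Run the full pipeline end to end
#'
#' Simulates the study inputs, parses cell alleles from the locus reads,
#' applies QC, annotates cell types and neuron classes, runs the full
#' contrast scaffold, performs gene-set enrichment on each contrast's
#' significant genes, detects co-expression modules with trait
#' correlations, and intersects mouse and human-like PCB-response DEGs per
#' broad cell class. Writes every stage's outputs under `out_dir` and a
#' `manifest.json` (written last) that records the configuration hash,
#' per-stage seeds, output files, and row counts.
#'
#' @param config path to a YAML configuration, a configuration list, or
#'   `NULL` for the demo defaults.
#' @param out_dir output directory (created; stages write into
#'   subdirectories).
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config = NULL, out_dir) {
  cfg <- .load_run_config(config)
  # validate everything before writing anything
  sim_cfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  params <- do.call(parser_params, cfg$parser)
  thr <- do.call(qc_thresholds, cfg$qc)
  np <- do.call(network_params,
                c(cfg$network, list(seed = cfg$seed)))
  hum_cfg <- do.call(human_sim_config,
                     c(cfg$human, list(seed = cfg$seed + 10L)))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "mosaicx",
                   version = as.character(utils::packageVersion("mosaicx")),
                   config_hash = cfg$config_hash, seed = cfg$seed,
                   stages = list())
  note <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(name = stage, files = files,
                                      rows = rows, seed = cfg$seed)
  }
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. simulate ------------------------------------------------------------
  d <- stage_dir("01_simulate")
  ref <- locus_reference()
  sim <- run_stage("simulate", function() {
    truth <- simulate_truth(sim_cfg)
    cnt <- simulate_counts(truth, sim_cfg)
    reads <- simulate_locus_reads(truth, ref, sim_cfg)
    list(truth = cnt$truth, counts = cnt, reads = reads)
  })
  write_tsv(sim$truth, file.path(d, "truth.tsv"))
  write_counts_mtx(sim$counts$counts, file.path(d, "counts"))
  write_fastq_pair(sim$reads, file.path(d, "locus_R1.fastq"),
                   file.path(d, "locus_R2.fastq"))
  write_locus_reference(ref, file.path(d, "locus.fasta"))
  gmt <- simulate_genesets(sim_cfg, sim$counts$deg_truth)
  write_gmt(gmt, file.path(d, "genesets.gmt"))
  orth <- simulate_ortholog_map(sim_cfg)
  write_tsv(orth$map, file.path(d, "orthologs.tsv"))
  note("simulate",
       c("truth.tsv", "counts/", "locus_R1.fastq", "locus_R2.fastq",
         "locus.fasta", "genesets.gmt", "orthologs.tsv"),
       nrow(sim$truth))

  # 2. parse ---------------------------------------------------------------
  d <- stage_dir("02_parse")
  parsed <- run_stage("parse", function() {
    parse_alleles(sim$reads, ref = ref, params = params)
  })
  write_tsv(parsed$cells, file.path(d, "cell_calls.tsv"))
  note("parse", "cell_calls.tsv", nrow(parsed$cells))

  # 3. qc ------------------------------------------------------------------
  d <- stage_dir("03_qc")
  qc <- run_stage("qc", function() {
    apply_qc(sim$counts$counts, sim$counts$cell_meta,
             sim$counts$gene_meta, thr)
  })
  write_tsv(data.frame(metric = names(qc$report),
                       value = unname(qc$report)),
            file.path(d, "qc_report.tsv"))
  note("qc", "qc_report.tsv", nrow(qc$cell_meta))

  # 4. annotate ------------------------------------------------------------
  d <- stage_dir("04_annotate")
  ann <- run_stage("annotate", function() {
    norm <- normalize_log(qc$counts)
    sig <- reference_signatures(norm, qc$cell_meta$cell_type,
                                sim_cfg$marker_genes)
    lt <- label_transfer(norm, sig)
    meta <- qc$cell_meta
    meta$cell_type <- lt$cell_type
    meta$type_confidence <- lt$confidence
    meta$neuron_class <- unname(.default_class_map[meta$cell_type])
    # merge the parsed allele calls by barcode (parser calls are per
    # barcode; barcodes are unique within sample in the simulation)
    calls <- parsed$cells$call[match(meta$barcode, parsed$cells$barcode)]
    calls[is.na(calls)] <- "UNASSIGNED"
    meta$allele <- ifelse(calls == "UNASSIGNED", NA_character_, calls)
    list(norm = norm, meta = meta)
  })
  write_tsv(ann$meta, file.path(d, "annotations.tsv"))
  note("annotate", "annotations.tsv", nrow(ann$meta))

  # 5. deg -----------------------------------------------------------------
  d <- stage_dir("05_deg")
  degs <- run_stage("deg", function() {
    specs <- rbind(enumerate_contrasts(parsed = TRUE),
                   enumerate_contrasts(parsed = FALSE))
    res <- list()
    for (i in seq_len(nrow(specs))) {
      tab <- run_contrast(qc$counts, ann$meta, specs[i, ],
                          seed = cfg$seed + i,
                          min_cells = cfg$deg$min_cells)
      if (!is.null(tab)) res[[specs$name[i]]] <- tab
    }
    res
  })
  for (nm in names(degs)) {
    write_tsv(degs[[nm]], file.path(d, paste0(nm, ".tsv")))
  }
  note("deg", paste0(names(degs), ".tsv"),
       sum(vapply(degs, nrow, 1L)))

  # 6. enrich --------------------------------------------------------------
  d <- stage_dir("06_enrich")
  enr <- run_stage("enrich", function() {
    background <- unique(unlist(gmt, use.names = FALSE))
    res <- list()
    for (nm in names(degs)) {
      tab <- degs[[nm]]
      sig <- intersect(tab$gene[!is.na(tab$padj) &
                                  tab$padj <= cfg$deg$fdr], background)
      if (length(sig)) res[[nm]] <- fisher_enrichment(sig, gmt, background)
    }
    res
  })
  for (nm in names(enr)) {
    write_tsv(enr[[nm]], file.path(d, paste0(nm, "_enrichment.tsv")))
  }
  sig_paths <- lapply(enr, function(tab) tab$set[tab$padj <= 0.05])
  sig_paths <- sig_paths[vapply(sig_paths, length, 1L) > 0]
  if (length(sig_paths)) {
    ups <- upset_exclusive_counts(sig_paths)
    write_tsv(data.frame(region = names(ups), count = unname(ups)),
              file.path(d, "pathway_upset.tsv"))
  }
  note("enrich", paste0(names(enr), "_enrichment.tsv"),
       sum(vapply(enr, nrow, 1L)))

  # 7. modules -------------------------------------------------------------
  d <- stage_dir("07_modules")
  mods <- run_stage("modules", function() {
    keep <- filter_network_genes(qc$counts, np$min_expr_fraction)
    norm <- ann$norm[, keep, drop = FALSE]
    adj <- build_network(norm, ann$meta$cell_type, np)
    assign <- detect_modules(adj, np)
    mlist <- setdiff(sort(unique(assign)), "grey")
    eg <- vapply(mlist, function(m) {
      module_eigengene(norm, names(assign)[assign == m])$eigengene
    }, numeric(nrow(norm)))
    traits <- data.frame(
      genotype = as.integer(ann$meta$genotype ==
                              utils::tail(sim_cfg$genotypes, 1L)),
      treatment = as.integer(ann$meta$treatment ==
                               utils::tail(sim_cfg$treatments, 1L)))
    mt <- if (length(mlist)) module_trait_correlation(eg, traits) else NULL
    ov <- if (length(mlist)) {
      module_marker_overlap(assign, sim_cfg$marker_genes)
    } else NULL
    list(assign = assign, trait = mt, overlap = ov)
  })
  write_tsv(data.frame(gene = names(mods$assign),
                       module = unname(mods$assign)),
            file.path(d, "module_assignments.tsv"))
  if (!is.null(mods$trait)) {
    write_tsv(mods$trait, file.path(d, "module_trait_correlation.tsv"))
  }
  if (!is.null(mods$overlap)) {
    write_tsv(mods$overlap, file.path(d, "module_marker_overlap.tsv"))
  }
  note("modules", "module_assignments.tsv", length(mods$assign))

  # 8. cross-species -------------------------------------------------------
  d <- stage_dir("08_cross_species")
  xs <- run_stage("cross_species", function() {
    # human-like cohort: 3 broad classes, PCB-exposure label
    htruth <- simulate_truth(hum_cfg)
    hcnt <- simulate_counts(htruth, hum_cfg)
    classes <- c("GABAergic", "Glutamatergic", "Non-neuronal")
    hdeg <- mdeg <- stats::setNames(vector("list", 3L), classes)
    for (cl in classes) {
      hrows <- hcnt$cell_meta$cell_type == cl
      tab <- .pcb_class_de(hcnt$counts[hrows, , drop = FALSE],
                           hcnt$cell_meta$treatment[hrows],
                           "PCB", cfg$seed)
      hdeg[[cl]] <- tab$gene[!is.na(tab$padj) & tab$padj <= cfg$deg$fdr]
      mrows <- ann$meta$genotype == "HET" & ann$meta$neuron_class == cl
      if (cl == "Non-neuronal") {
        mrows <- ann$meta$genotype == "HET" &
          .default_class_map[ann$meta$cell_type] == "Non-neuronal"
      }
      mtab <- .pcb_class_de(qc$counts[mrows, , drop = FALSE],
                            ann$meta$treatment[mrows], "PCB", cfg$seed)
      mdeg[[cl]] <- mtab$gene[!is.na(mtab$padj) & mtab$padj <= cfg$deg$fdr]
    }
    list(res = intersect_cross_species(hdeg, mdeg, orth$map),
         hdeg = hdeg, mdeg = mdeg)
  })
  xs_tab <- do.call(rbind, lapply(names(xs$res), function(cl) {
    data.frame(class = cl,
               n_human_mapped = xs$res[[cl]]$n_human_mapped,
               n_mouse = xs$res[[cl]]$n_mouse,
               n_intersection = length(xs$res[[cl]]$intersection),
               stringsAsFactors = FALSE)
  }))
  write_tsv(xs_tab, file.path(d, "cross_species_intersections.tsv"))
  note("cross_species", "cross_species_intersections.tsv", nrow(xs_tab))

  manifest$stages <- unname(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# PCB-vs-control DE within one broad class, downsampled to equal sizes.
.pcb_class_de <- function(counts, treatment, pcb_level, seed) {
  ia <- which(treatment != pcb_level)
  ib <- which(treatment == pcb_level)
  if (length(ia) < 2L || length(ib) < 2L) {
    return(data.frame(gene = character(0), log2fc = numeric(0),
                      p = numeric(0), padj = numeric(0)))
  }
  ds <- downsample_equal(ia, ib, seed = seed)
  lib <- rowSums(counts)
  res <- lapply(colnames(counts), function(g) {
    nb_test_gene(counts[ds$a, g], counts[ds$b, g], lib[ds$a], lib[ds$b])
  })
  out <- data.frame(gene = colnames(counts),
                    log2fc = vapply(res, `[[`, 1, "log2fc"),
                    p = vapply(res, `[[`, 1, "p"),
                    stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  out
}
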