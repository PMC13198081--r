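# Mosaic contrast design and negative-binomial DE --------------------------
#
# The study's comparison scaffold: 4 bulk group contrasts (genotype within
# each treatment, treatment within each genotype) and, once cells are
# parsed into wild-type- and mutant-allele-expressing, 15 neuronal
# comparisons over GABAergic and glutamatergic classes. Sides are
# downsampled to equal size, and each gene is tested with a negative
# binomial model whose mean is library size times relative abundance.

# The parsed design, encoded as data. Prose constraints: experiments are
# bulk (non-parsed) HET and WT treatment responses per neuron class;
# mutant- vs wild-type-expressing cells within HET under each treatment;
# the treatment response of wild-type-expressing HET cells; the
# non-cell-autonomous comparison of wild-type-expressing HET cells against
# WT-cortex cells under each treatment; and the treatment response of
# mutant-expressing cells (GABAergic). "ANY" matches any allele, including
# unparsed; parsed rows exclude UNASSIGNED cells by construction.
.parsed_design_table <- function() {
  r <- function(name, class, parsed, ag, at, aa, bg, bt, ba) {
    data.frame(name = name, neuron_class = class, parsed = parsed,
               a_genotype = ag, a_treatment = at, a_allele = aa,
               b_genotype = bg, b_treatment = bt, b_allele = ba,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # bulk (non-parsed) treatment responses per neuron class
    r("HET_PCBvsVEH_Glut_bulk", "Glutamatergic", FALSE,
      "HET", "VEH", "ANY", "HET", "PCB", "ANY"),
    r("HET_PCBvsVEH_GABA_bulk", "GABAergic", FALSE,
      "HET", "VEH", "ANY", "HET", "PCB", "ANY"),
    r("WT_PCBvsVEH_Glut_bulk", "Glutamatergic", FALSE,
      "WT", "VEH", "ANY", "WT", "PCB", "ANY"),
    r("WT_PCBvsVEH_GABA_bulk", "GABAergic", FALSE,
      "WT", "VEH", "ANY", "WT", "PCB", "ANY"),
    # parsed: mutant- vs wild-type-expressing within HET, per treatment
    r("HETVEH_MUTvsWT_Glut", "Glutamatergic", TRUE,
      "HET", "VEH", "WT", "HET", "VEH", "MUT"),
    r("HETVEH_MUTvsWT_GABA", "GABAergic", TRUE,
      "HET", "VEH", "WT", "HET", "VEH", "MUT"),
    r("HETPCB_MUTvsWT_Glut", "Glutamatergic", TRUE,
      "HET", "PCB", "WT", "HET", "PCB", "MUT"),
    r("HETPCB_MUTvsWT_GABA", "GABAergic", TRUE,
      "HET", "PCB", "WT", "HET", "PCB", "MUT"),
    # parsed: treatment response of wild-type-expressing HET cells
    r("HETWTexpr_PCBvsVEH_Glut", "Glutamatergic", TRUE,
      "HET", "VEH", "WT", "HET", "PCB", "WT"),
    r("HETWTexpr_PCBvsVEH_GABA", "GABAergic", TRUE,
      "HET", "VEH", "WT", "HET", "PCB", "WT"),
    # parsed: treatment response of mutant-expressing HET cells (GABAergic)
    r("HETMUTexpr_PCBvsVEH_GABA", "GABAergic", TRUE,
      "HET", "VEH", "MUT", "HET", "PCB", "MUT"),
    # parsed, non-cell-autonomous: wild-type-expressing HET cells vs
    # WT-cortex cells, within each treatment
    r("VEH_HETWTexprVsWT_Glut", "Glutamatergic", TRUE,
      "WT", "VEH", "WT", "HET", "VEH", "WT"),
    r("VEH_HETWTexprVsWT_GABA", "GABAergic", TRUE,
      "WT", "VEH", "WT", "HET", "VEH", "WT"),
    r("PCB_HETWTexprVsWT_Glut", "Glutamatergic", TRUE,
      "WT", "PCB", "WT", "HET", "PCB", "WT"),
    r("PCB_HETWTexprVsWT_GABA", "GABAergic", TRUE,
      "WT", "PCB", "WT", "HET", "PCB", "WT")))
}

#' Enumerate the study's contrast scaffold
#'
#' With allele parsing on, returns the 15 parsed neuronal comparisons
#' (optionally restricted to one neuron class); with parsing off, the 4
#' bulk group comparisons (genotype within each treatment, treatment
#' within each genotype, over all cell types).
#'
#' @param genotypes,treatments design levels; must contain WT/HET and
#'   VEH/PCB respectively.
#' @param neuron_classes classes to include (subset of
#'   GABAergic / Glutamatergic).
#' @param parsed logical: allele parsing enabled?
#' @return data.frame of contrast specifications; one row per comparison,
#'   with side A and side B selection predicates.
#' @export
enumerate_contrasts <- function(genotypes = c("WT", "HET"),
                                treatments = c("VEH", "PCB"),
                                neuron_classes = c("GABAergic",
                                                   "Glutamatergic"),
                                parsed = TRUE) {
  if (!all(genotypes %in% c("WT", "HET"))) {
    stop("unknown genotype value(s): ",
         paste(setdiff(genotypes, c("WT", "HET")), collapse = ", "),
         call. = FALSE)
  }
  if (!all(treatments %in% c("VEH", "PCB"))) {
    stop("unknown treatment value(s): ",
         paste(setdiff(treatments, c("VEH", "PCB")), collapse = ", "),
         call. = FALSE)
  }
  if (!all(neuron_classes %in% c("GABAergic", "Glutamatergic"))) {
    stop("unknown neuron class value(s): ",
         paste(setdiff(neuron_classes, c("GABAergic", "Glutamatergic")),
               collapse = ", "), call. = FALSE)
  }
  if (parsed) {
    d <- .parsed_design_table()
    d <- d[d$neuron_class %in% neuron_classes &
             d$a_genotype %in% genotypes & d$b_genotype %in% genotypes &
             d$a_treatment %in% treatments &
             d$b_treatment %in% treatments, , drop = FALSE]
  } else {
    combos <- list(
      c("VEHgroup_WTvsHET", "WT", "VEH", "HET", "VEH"),
      c("PCBgroup_WTvsHET", "WT", "PCB", "HET", "PCB"),
      c("WTgroup_VEHvsPCB", "WT", "VEH", "WT", "PCB"),
      c("HETgroup_VEHvsPCB", "HET", "VEH", "HET", "PCB"))
    d <- do.call(rbind, lapply(combos, function(x) {
      data.frame(name = x[1], neuron_class = "ANY", parsed = FALSE,
                 a_genotype = x[2], a_treatment = x[3], a_allele = "ANY",
                 b_genotype = x[4], b_treatment = x[5], b_allele = "ANY",
                 stringsAsFactors = FALSE)
    }))
    d <- d[d$a_genotype %in% genotypes & d$b_genotype %in% genotypes &
             d$a_treatment %in% treatments &
             d$b_treatment %in% treatments, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

# Select the cells matching one side of a contrast.
.select_side <- function(cell_meta, genotype, treatment, allele,
                         neuron_class, class_map) {
  sel <- cell_meta$genotype == genotype & cell_meta$treatment == treatment
  if (allele != "ANY") {
    sel <- sel & !is.na(cell_meta$allele) & cell_meta$allele == allele
  }
  if (neuron_class != "ANY") {
    sel <- sel & class_map[cell_meta$cell_type] == neuron_class
  }
  which(sel)
}

#' Downsample two cell selections to equal size
#'
#' Both sides are reduced to the size of the smaller one by sampling
#' without replacement, reproducibly for a given seed.
#'
#' @param idx_a,idx_b integer indices of the two sides.
#' @param seed integer seed.
#' @return list with equal-length `a` and `b`.
#' @export
downsample_equal <- function(idx_a, idx_b, seed = 1L) {
  if (length(idx_a) == 0L || length(idx_b) == 0L) {
    stop("cannot downsample an empty side", call. = FALSE)
  }
  n <- min(length(idx_a), length(idx_b))
  set.seed(seed)
  list(a = sort(sample(idx_a, n)), b = sort(sample(idx_b, n)))
}

#' Negative-binomial test for one gene
#'
#' Fits `count ~ group` with a log link and `log(library size)` offset.
#' The gene-wise dispersion `alpha` (variance `mu + alpha mu^2`) is
#' estimated by method of moments from the two sides' residuals and floored
#' at 1e-8; the group coefficient is the log fold change (B over A) and its
#' Wald test gives the p value. Genes expressed on neither side are
#' untestable (all-NA result). Non-converging NB fits fall back to a
#' Poisson fit and are flagged.
#'
#' @param counts_a,counts_b per-cell counts on the two sides.
#' @param lib_a,lib_b matching library sizes.
#' @return list with `log2fc`, `p`, `alpha`, `mean_abundance`, `flagged`.
#' @export
nb_test_gene <- function(counts_a, counts_b, lib_a, lib_b) {
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("need at least 2 cells per side", call. = FALSE)
  }
  if (sum(counts_a) == 0 && sum(counts_b) == 0) {
    return(list(log2fc = NA_real_, p = NA_real_, alpha = NA_real_,
                mean_abundance = 0, flagged = FALSE))
  }
  y <- c(counts_a, counts_b)
  lib <- c(lib_a, lib_b)
  grp <- rep(c(0, 1), c(length(counts_a), length(counts_b)))
  # method-of-moments dispersion around group-specific abundances
  qa <- sum(counts_a) / sum(lib_a)
  qb <- sum(counts_b) / sum(lib_b)
  mu <- lib * ifelse(grp == 0, qa, qb)
  alpha <- max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-8)
  fit <- tryCatch(
    suppressWarnings(glm(y ~ grp + offset(log(lib)),
                         family = MASS::negative.binomial(theta = 1 / alpha))),
    error = function(e) NULL)
  flagged <- FALSE
  if (is.null(fit) || !fit$converged) {
    fit <- suppressWarnings(glm(y ~ grp + offset(log(lib)),
                                family = stats::poisson()))
    flagged <- TRUE
  }
  beta <- coef(fit)[["grp"]]
  se <- sqrt(vcov(fit)["grp", "grp"])
  p <- 2 * pnorm(-abs(beta / se))
  list(log2fc = beta / log(2), p = p, alpha = alpha,
       mean_abundance = mean(y / lib), flagged = flagged)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; NA / NaN entries are excluded from the
#' number of tests and propagated unchanged.
#'
#' @param p vector of p values in `[0, 1]` (NAs allowed).
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Run one contrast of the scaffold
#'
#' Selects the two cell sides (parsed sides exclude UNASSIGNED cells by
#' requiring an explicit allele), downsamples them to equal size, tests
#' every gene with [nb_test_gene()], and applies [bh_adjust()].
#'
#' @param counts cells-by-genes count matrix.
#' @param cell_meta per-cell annotations with `genotype`, `treatment`,
#'   `allele`, `cell_type`.
#' @param spec one row of [enumerate_contrasts()].
#' @param class_map named map from cell type to neuron class (defaults to
#'   the synthetic cortex types).
#' @param seed downsampling seed (recorded in the output attributes).
#' @param min_cells sides smaller than this skip the contrast (returns
#'   `NULL` with a message).
#' @return data.frame of class `deg_result`: `gene`, `log2fc`, `p`, `padj`,
#'   `mean_abundance`, `n_a`, `n_b`, `flagged`; or `NULL` when a side is
#'   empty/too small.
#' @export
run_contrast <- function(counts, cell_meta, spec,
                         class_map = .default_class_map, seed = 1L,
                         min_cells = 2L) {
  if (is.data.frame(spec)) spec <- as.list(spec[1L, ])
  ia <- .select_side(cell_meta, spec$a_genotype, spec$a_treatment,
                     spec$a_allele, spec$neuron_class, class_map)
  ib <- .select_side(cell_meta, spec$b_genotype, spec$b_treatment,
                     spec$b_allele, spec$neuron_class, class_map)
  if (length(ia) < min_cells || length(ib) < min_cells) {
    message("contrast '", spec$name, "' skipped: a side has fewer than ",
            min_cells, " cells (", length(ia), " vs ", length(ib), ")")
    return(NULL)
  }
  ds <- downsample_equal(ia, ib, seed = seed)
  lib <- rowSums(counts)
  genes <- colnames(counts)
  res <- lapply(genes, function(g) {
    nb_test_gene(counts[ds$a, g], counts[ds$b, g], lib[ds$a], lib[ds$b])
  })
  out <- data.frame(gene = genes,
                    log2fc = vapply(res, `[[`, 1, "log2fc"),
                    p = vapply(res, `[[`, 1, "p"),
                    mean_abundance = vapply(res, `[[`, 1,
                                            "mean_abundance"),
                    n_a = length(ds$a), n_b = length(ds$b),
                    flagged = vapply(res, `[[`, TRUE, "flagged"),
                    stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  out <- out[, c("gene", "log2fc", "p", "padj", "mean_abundance",
                 "n_a", "n_b", "flagged")]
  attr(out, "contrast") <- spec$name
  attr(out, "seed") <- seed
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Select top heatmap genes from a DEG table
#'
#' Significant genes (adjusted p <= `fdr`) ranked by absolute log2 fold
#' change, ties broken by gene identifier; at most `k` genes.
#'
#' @param results a `deg_result` table.
#' @param k maximum genes to return.
#' @param fdr significance threshold on the adjusted p value.
#' @return character vector of gene identifiers (possibly shorter than
#'   `k`; empty with a warning when nothing is significant).
#' @export
select_heatmap_genes <- function(results, k, fdr = 0.05) {
  sig <- results[!is.na(results$padj) & results$padj <= fdr, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no significant genes to select", call. = FALSE)
    return(character(0))
  }
  sig <- sig[order(-abs(sig$log2fc), sig$gene), , drop = FALSE]
  head(sig$gene, k)
}

#' Cell-type proportion shift test
#'
#' Per cell type, a chi-square test of the (type vs all other cells) by
#' condition contingency table, BH-adjusted across types.
#'
#' @param labels per-cell type labels.
#' @param condition per-cell condition labels (>= 2 levels, each with
#'   cells).
#' @return data.frame with `cell_type`, `p`, `padj`.
#' @export
proportion_test <- function(labels, condition) {
  stopifnot(length(labels) == length(condition))
  conds <- unique(condition)
  if (length(conds) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (any(table(factor(condition, levels = conds)) == 0)) {
    stop("a condition has zero cells", call. = FALSE)
  }
  types <- sort(unique(labels))
  p <- vapply(types, function(ty) {
    tab <- rbind(table(factor(condition[labels == ty], levels = conds)),
                 table(factor(condition[labels != ty], levels = conds)))
    if (length(types) == 1L || any(rowSums(tab) == 0)) return(1)
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  data.frame(cell_type = types, p = unname(p), padj = bh_adjust(unname(p)),
             stringsAsFactors = FALSE)
}
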