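# QC, normalization, and cell-type annotation -----------------------------

#' QC thresholds
#'
#' Defaults encode the filter used for the emulated study: mitochondrial
#' fraction strictly below 7%, 200-5625 expressed genes (inclusive), and
#' 208-16300 UMIs (inclusive).
#'
#' @param max_mito_fraction exclusive upper bound on mitochondrial fraction.
#' @param min_genes,max_genes inclusive bounds on expressed genes.
#' @param min_umi,max_umi inclusive bounds on total UMIs.
#' @return a validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.07, min_genes = 200L,
                          max_genes = 5625L, min_umi = 208L,
                          max_umi = 16300L) {
  .check_scalar(max_mito_fraction, "max_mito_fraction", 0, 1)
  if (min_genes >= max_genes || min_umi >= max_umi) {
    stop("configuration error: QC minima must be below maxima",
         call. = FALSE)
  }
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 min_umi = as.integer(min_umi),
                 max_umi = as.integer(max_umi)),
            class = "qc_thresholds")
}

# Ensure cell_meta carries QC metrics consistent with the counts.
.with_qc_metrics <- function(counts, cell_meta, gene_meta) {
  n_umi <- as.integer(rowSums(counts))
  n_genes <- as.integer(rowSums(counts > 0))
  mito <- gene_meta$gene[gene_meta$is_mito]
  mito_frac <- if (length(mito)) {
    rowSums(counts[, mito, drop = FALSE]) / pmax(n_umi, 1L)
  } else rep(0, nrow(counts))
  cell_meta$n_umi <- n_umi
  cell_meta$n_genes <- n_genes
  cell_meta$mito_fraction <- mito_frac
  cell_meta
}

#' Apply QC filters to an annotated count matrix
#'
#' Retains exactly the cells with mitochondrial fraction strictly below the
#' bound and gene / UMI totals within the inclusive bounds. Metrics are
#' (re)computed from the raw counts. A pure filter: retained rows are
#' unchanged and keep their order.
#'
#' @param counts cells-by-genes count matrix.
#' @param cell_meta per-cell annotation data.frame (row order matches
#'   `counts`).
#' @param gene_meta per-gene annotation with `gene` and `is_mito`.
#' @param thr a [qc_thresholds()].
#' @return list with filtered `counts` and `cell_meta`, plus `report`: per
#'   criterion, how many cells violated it (cells can violate several), and
#'   totals.
#' @export
apply_qc <- function(counts, cell_meta, gene_meta, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"), nrow(counts) == nrow(cell_meta))
  cell_meta <- .with_qc_metrics(counts, cell_meta, gene_meta)
  bad_mito <- cell_meta$mito_fraction >= thr$max_mito_fraction
  bad_genes <- cell_meta$n_genes < thr$min_genes |
    cell_meta$n_genes > thr$max_genes
  bad_umi <- cell_meta$n_umi < thr$min_umi | cell_meta$n_umi > thr$max_umi
  keep <- !(bad_mito | bad_genes | bad_umi)
  if (!any(keep)) warning("QC removed every cell", call. = FALSE)
  report <- c(n_input = nrow(counts),
              removed_mito = sum(bad_mito),
              removed_genes = sum(bad_genes),
              removed_umi = sum(bad_umi),
              removed_total = sum(!keep),
              n_retained = sum(keep))
  list(counts = counts[keep, , drop = FALSE],
       cell_meta = cell_meta[keep, , drop = FALSE],
       report = report)
}

#' Library-size normalize and log-transform counts
#'
#' `log(1 + count * target_sum / library_size)` per cell (natural log,
#' target 10,000 by default).
#'
#' @param counts cells-by-genes count matrix.
#' @param target_sum per-cell scaling target.
#' @return normalized matrix of the same shape.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    stop("cells with zero library size cannot be normalized; filter first",
         call. = FALSE)
  }
  log1p(counts * (target_sum / lib))
}

#' Z-score genes across cells
#'
#' Per-gene standardization of a normalized matrix, clipped at +/-`clip`;
#' genes with zero variance scale to all zeros.
#'
#' @param normalized output of [normalize_log()].
#' @param clip symmetric clipping bound on z-scores.
#' @return scaled matrix of the same shape.
#' @export
scale_genes <- function(normalized, clip = 10) {
  mu <- colMeans(normalized)
  s <- apply(normalized, 2L, stats::sd)
  z <- sweep(normalized, 2L, mu, "-")
  nz <- s > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, s[nz], "/")
  z[, !nz] <- 0
  pmin(pmax(z, -clip), clip)
}

#' Build reference signatures from labeled cells
#'
#' Mean normalized profile per cell type, plus the marker list per type
#' when supplied.
#'
#' @param normalized normalized matrix (cells x genes).
#' @param labels per-cell type labels.
#' @param markers optional named list of marker genes per type.
#' @return list of class `reference_signatures` with `profiles`
#'   (types x genes) and `markers`.
#' @export
reference_signatures <- function(normalized, labels, markers = NULL) {
  stopifnot(length(labels) == nrow(normalized))
  types <- sort(unique(labels))
  prof <- t(vapply(types, function(ty) {
    colMeans(normalized[labels == ty, , drop = FALSE])
  }, numeric(ncol(normalized))))
  rownames(prof) <- types
  if (any(!is.finite(prof))) stop("non-finite signature profile",
                                  call. = FALSE)
  structure(list(profiles = prof, markers = markers),
            class = "reference_signatures")
}

#' Nearest-centroid label transfer
#'
#' Labels each cell with the reference type whose signature profile it
#' correlates with most (Pearson, over the shared gene space); confidence
#' is the margin between the top correlation and the runner-up. Exact ties
#' resolve to the lexicographically first type name.
#'
#' @param normalized normalized matrix (cells x genes).
#' @param ref a [reference_signatures()].
#' @return data.frame with `cell_type` and `confidence` per cell.
#' @export
label_transfer <- function(normalized, ref) {
  stopifnot(inherits(ref, "reference_signatures"))
  shared <- intersect(colnames(normalized), colnames(ref$profiles))
  if (length(shared) == 0L) {
    stop("no genes shared between data and reference signatures",
         call. = FALSE)
  }
  prof <- ref$profiles[, shared, drop = FALSE]
  # drop reference genes that are constant across cells (undefined cor)
  keepg <- apply(normalized[, shared, drop = FALSE], 2L, stats::sd) > 0
  if (!any(keepg)) stop("all shared genes are constant", call. = FALSE)
  r <- suppressWarnings(
    cor(t(as.matrix(normalized[, shared, drop = FALSE][, keepg,
                                                       drop = FALSE])),
        t(prof[, keepg, drop = FALSE])))
  r[is.na(r)] <- -Inf
  ord <- order(colnames(r))  # lexicographic tie-break via first max
  r <- r[, ord, drop = FALSE]
  best <- max.col(r, ties.method = "first")
  conf <- vapply(seq_len(nrow(r)), function(i) {
    v <- sort(r[i, ], decreasing = TRUE)
    if (length(v) > 1L) v[1L] - v[2L] else v[1L]
  }, numeric(1))
  data.frame(cell_type = colnames(r)[best], confidence = conf,
             stringsAsFactors = FALSE)
}

#' Marker summary statistics per (gene, cell type)
#'
#' For each requested marker gene and type: the percentage of the type's
#' cells expressing the gene (count > 0) and the mean scaled (z-score)
#' expression, the two quantities shown in marker dot plots.
#'
#' @param normalized normalized matrix (cells x genes).
#' @param counts raw counts (same shape) used for the detection percentage.
#' @param labels per-cell type labels.
#' @param markers character vector of genes to summarize.
#' @return data.frame with `gene`, `cell_type`, `pct_expressing`,
#'   `mean_scaled_expression`.
#' @export
marker_stats <- function(normalized, counts, labels, markers) {
  stopifnot(length(labels) == nrow(normalized),
            all(dim(normalized) == dim(counts)))
  if (!all(markers %in% colnames(normalized))) {
    stop("unknown marker gene(s): ",
         paste(setdiff(markers, colnames(normalized)), collapse = ", "),
         call. = FALSE)
  }
  scaled <- scale_genes(normalized[, markers, drop = FALSE])
  types <- sort(unique(labels))
  out <- expand.grid(gene = markers, cell_type = types,
                     stringsAsFactors = FALSE)
  out$pct_expressing <- NA_real_
  out$mean_scaled_expression <- NA_real_
  for (ty in types) {
    rows <- labels == ty
    i <- out$cell_type == ty
    out$pct_expressing[i] <-
      100 * colMeans(counts[rows, markers, drop = FALSE] > 0)
    out$mean_scaled_expression[i] <-
      colMeans(scaled[rows, , drop = FALSE])
  }
  out
}

#' K-means view of the normalized data (sanity check only)
#'
#' Optional unsupervised view for eyeballing cluster structure; the
#' pipeline's cell typing uses [label_transfer()], which is deterministic.
#'
#' @param normalized normalized matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @return integer cluster assignment per cell.
#' @export
kmeans_view <- function(normalized, k, seed = 1L) {
  set.seed(seed)
  stats::kmeans(normalized, centers = k, nstart = 5L)$cluster
}
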