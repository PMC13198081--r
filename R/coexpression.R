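# Signed co-expression network modules -------------------------------------
#
# Desk-scale signed network analysis: genes passing an expression-fraction
# filter are correlated over pseudocells (random disjoint pools of
# same-type cells, which play the variance-reduction role of metacells),
# the correlation is soft-thresholded into a signed adjacency, modules are
# cut from average-linkage clustering of the topological-overlap
# dissimilarity, and each module is summarized by its eigengene, hub genes,
# rank-based per-cell scores, and trait correlations.

#' Network parameters
#'
#' @param min_expr_fraction genes must be expressed (count > 0) in at least
#'   this fraction of cells.
#' @param soft_power signed soft-threshold exponent beta; adjacency is
#'   `((1 + r) / 2)^beta`.
#' @param pooling_size same-type cells averaged per pseudocell.
#' @param min_module_size clusters below this size go to the grey
#'   (unassigned) module.
#' @param cut_height fixed tree-cut height on the topological-overlap
#'   dissimilarity dendrogram.
#' @param seed RNG seed for the random pooling.
#' @return a validated list of class `network_params`.
#' @export
network_params <- function(min_expr_fraction = 0.05, soft_power = 8,
                           pooling_size = 20L, min_module_size = 30L,
                           cut_height = 0.98, seed = 1L) {
  .check_scalar(min_expr_fraction, "min_expr_fraction", 0, 1)
  .check_scalar(soft_power, "soft_power", 1e-8, Inf)
  .check_scalar(pooling_size, "pooling_size", 1, Inf, TRUE)
  .check_scalar(min_module_size, "min_module_size", 1, Inf, TRUE)
  .check_scalar(cut_height, "cut_height", 0, 1)
  structure(list(min_expr_fraction = min_expr_fraction,
                 soft_power = soft_power,
                 pooling_size = as.integer(pooling_size),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, seed = as.integer(seed)),
            class = "network_params")
}

#' Filter genes by expression fraction
#'
#' @param counts cells-by-genes counts.
#' @param min_expr_fraction minimum fraction of cells with count > 0.
#' @return character vector of passing genes.
#' @export
filter_network_genes <- function(counts, min_expr_fraction = 0.05) {
  frac <- colMeans(counts > 0)
  colnames(counts)[frac >= min_expr_fraction]
}

# Random disjoint pooling of same-type cells into pseudocell averages.
# Cells are ordered by identity (rownames) before the seeded shuffle so the
# pooling -- and hence the network -- does not depend on input row order.
.pool_pseudocells <- function(normalized, cell_types, pooling_size, seed) {
  set.seed(seed)
  ord <- seq_len(nrow(normalized))
  if (!is.null(rownames(normalized))) {
    ord <- order(rownames(normalized))
  }
  groups <- split(ord, cell_types[ord])
  pools <- list()
  for (g in groups) {
    g <- sample(g)
    n_full <- length(g) %/% pooling_size
    if (n_full == 0L) next
    for (i in seq_len(n_full)) {
      pools[[length(pools) + 1L]] <-
        g[((i - 1L) * pooling_size + 1L):(i * pooling_size)]
    }
  }
  if (length(pools) < 3L) {
    stop("fewer than 3 pseudocells; decrease pooling_size or add cells",
         call. = FALSE)
  }
  t(vapply(pools, function(ix) {
    colMeans(normalized[ix, , drop = FALSE])
  }, numeric(ncol(normalized))))
}

#' Build a signed co-expression adjacency
#'
#' Pools cells into pseudocells, computes pseudocell Pearson correlations,
#' and maps them through the signed soft threshold
#' `a_ij = ((1 + r_ij) / 2)^beta` (diagonal 1). Genes with zero pseudocell
#' variance get zero correlation to every other gene.
#'
#' @param normalized normalized matrix (cells x genes), already restricted
#'   to genes passing [filter_network_genes()].
#' @param cell_types per-cell type labels used for same-type pooling
#'   (a single label pools across all cells).
#' @param params a [network_params()].
#' @return genes-by-genes adjacency matrix in `[0, 1]`.
#' @export
build_network <- function(normalized, cell_types = NULL,
                          params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  if (is.null(cell_types)) cell_types <- rep("all", nrow(normalized))
  pooled <- .pool_pseudocells(normalized, cell_types, params$pooling_size,
                              params$seed)
  r <- suppressWarnings(cor(pooled))
  r[is.na(r)] <- 0
  a <- ((1 + r) / 2)^params$soft_power
  diag(a) <- 1
  dimnames(a) <- list(colnames(normalized), colnames(normalized))
  a
}

# Topological overlap matrix of a symmetric adjacency with unit diagonal.
.tom <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect modules from a signed adjacency
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity, cut at a fixed height; clusters below the minimum module
#' size become grey (unassigned). Modules are labelled `M1`, `M2`, ... in
#' decreasing size order, deterministically.
#'
#' @param adjacency output of [build_network()].
#' @param params a [network_params()].
#' @return named character vector: gene -> module label ("grey" =
#'   unassigned).
#' @export
detect_modules <- function(adjacency, params = network_params()) {
  stopifnot(inherits(params, "network_params"),
            nrow(adjacency) == ncol(adjacency))
  diss <- 1 - .tom(adjacency)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  labels <- rep("grey", nrow(adjacency))
  names(labels) <- rownames(adjacency)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) {
      labels[cl == as.integer(keep[i])] <- sprintf("M%d", i)
    }
  }
  labels
}

#' Module eigengene
#'
#' First principal component of the module's z-scored expression across
#' cells, unit-norm, with its sign aligned so the mean correlation with the
#' module's genes is positive. A single-gene module returns that gene's
#' scaled profile (normalized to unit norm).
#'
#' @param normalized normalized matrix (cells x genes).
#' @param module_genes genes in the module (non-empty).
#' @return list with `eigengene` (per-cell, unit norm), `var_explained`,
#'   and `kme` (per-module-gene correlation with the eigengene).
#' @export
module_eigengene <- function(normalized, module_genes) {
  if (length(module_genes) == 0L) stop("empty module", call. = FALSE)
  x <- scale_genes(normalized[, module_genes, drop = FALSE])
  if (length(module_genes) == 1L) {
    v <- x[, 1L]
    e <- if (sum(v^2) > 0) v / sqrt(sum(v^2)) else v
    return(list(eigengene = e, var_explained = 1,
                kme = stats::setNames(1, module_genes)))
  }
  sv <- svd(x, nu = 1L, nv = 0L)
  e <- sv$u[, 1L]
  kme <- suppressWarnings(cor(e, x))[1L, ]
  kme[is.na(kme)] <- 0
  if (mean(kme) < 0) {
    e <- -e
    kme <- -kme
  }
  list(eigengene = e,
       var_explained = sv$d[1L]^2 / sum(sv$d^2),
       kme = stats::setNames(kme, module_genes))
}

#' Rank hub genes by module membership (kME)
#'
#' @param normalized normalized matrix.
#' @param assignments gene -> module map from [detect_modules()].
#' @param n_hubs hub genes reported per module.
#' @return data.frame with `module`, `gene`, `kme`, ordered by module then
#'   decreasing kME.
#' @export
kme_hubs <- function(normalized, assignments, n_hubs = 10L) {
  mods <- setdiff(sort(unique(assignments)), "grey")
  do.call(rbind, lapply(mods, function(m) {
    genes <- names(assignments)[assignments == m]
    eg <- module_eigengene(normalized, genes)
    kme <- sort(eg$kme, decreasing = TRUE)
    head(data.frame(module = m, gene = names(kme), kme = unname(kme),
                    stringsAsFactors = FALSE), n_hubs)
  }))
}

#' Rank-based per-cell module score
#'
#' Mann-Whitney-U signature score on within-cell expression ranks
#' (decreasing expression, ties averaged) with a rank ceiling: ranks beyond
#' `max_rank` are truncated to it. The score is
#' `1 - U / (n (max_rank - n))`, clipped to `[0, 1]`; 1 when the module's
#' genes occupy the top `n` ranks, 0 when they all sit at or beyond the
#' ceiling.
#'
#' @param expression per-cell expression vector (named by gene) or
#'   cells-by-genes matrix.
#' @param module_genes module gene identifiers (must be fewer than
#'   `max_rank`).
#' @param max_rank rank ceiling.
#' @return numeric score per cell.
#' @export
rank_module_score <- function(expression, module_genes, max_rank = 1500L) {
  if (is.matrix(expression) || is.data.frame(expression)) {
    return(apply(as.matrix(expression), 1L, rank_module_score,
                 module_genes = module_genes, max_rank = max_rank))
  }
  n <- length(module_genes)
  if (n >= max_rank) {
    stop("module size must be below max_rank", call. = FALSE)
  }
  if (!all(module_genes %in% names(expression))) {
    stop("module genes missing from the expression vector", call. = FALSE)
  }
  rk <- rank(-expression, ties.method = "average")
  rk <- pmin(rk, max_rank)
  u <- sum(rk[module_genes]) - n * (n + 1) / 2
  min(1, max(0, 1 - u / (n * (max_rank - n))))
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each numeric-encoded
#' trait, with BH adjustment across all (module, trait) pairs. Constant
#' traits give NA correlation and are excluded from the adjustment.
#'
#' @param eigengenes cells-by-modules matrix of eigengene values.
#' @param traits cells-by-traits numeric matrix or data.frame (binary 0/1
#'   encodings for categorical variables).
#' @return data.frame with `module`, `trait`, `r`, `p`, `padj`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  eigengenes <- as.matrix(eigengenes)
  traits <- as.matrix(traits)
  stopifnot(nrow(eigengenes) == nrow(traits))
  grid <- expand.grid(module = colnames(eigengenes),
                      trait = colnames(traits), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- eigengenes[, grid$module[i]]
    y <- traits[, grid$trait[i]]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  grid$r <- vapply(res, `[[`, 1, "r")
  grid$p <- vapply(res, `[[`, 1, "p")
  grid$padj <- bh_adjust(grid$p)
  grid
}

#' Overlap of modules with cell-type marker sets
#'
#' Fisher-exact over-representation of each marker set within each module,
#' with the network gene set as background; delegates to
#' [fisher_enrichment()].
#'
#' @param assignments gene -> module map from [detect_modules()].
#' @param markers named list of marker gene sets.
#' @return data.frame: per (module, marker set) enrichment results.
#' @export
module_marker_overlap <- function(assignments, markers) {
  background <- names(assignments)
  mods <- setdiff(sort(unique(assignments)), "grey")
  do.call(rbind, lapply(mods, function(m) {
    res <- fisher_enrichment(names(assignments)[assignments == m],
                             markers, background)
    res$module <- m
    res[, c("module", setdiff(names(res), "module"))]
  }))
}
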