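# Fisher-exact gene-set enrichment and exclusive intersections -------------

# Two-sided Fisher exact p for a 2x2 table (a, b, c, d): the sum of
# hypergeometric probabilities of all tables with the observed margins
# whose probability does not exceed the observed one (standard convention).
.fisher_two_sided <- function(a, b, c, d) {
  m <- a + c          # elements in the set
  n <- b + d          # elements outside the set
  k <- a + b          # elements drawn (DEGs)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  supp <- lo:hi
  probs <- dhyper(supp, m, n, k)
  p_obs <- probs[supp == a]
  # relative tolerance mirrors the usual handling of ties in floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Cross-product odds ratio and Wald 95% CI on the log odds ratio. The
# reported OR is the raw cross-product (so zero overlap reports OR 0,
# i.e. depletion); when any cell is zero the CI is computed from
# Haldane-Anscombe +0.5-corrected cells, since the raw log OR is then
# unbounded.
.odds_ratio_ci <- function(a, b, c, d, conf = 0.95) {
  or <- (a * d) / (b * c)
  if (is.nan(or)) or <- 1  # 0/0: no information
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or_ci <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  c(or = or, lo = exp(log(or_ci) - zq * se),
    hi = exp(log(or_ci) + zq * se))
}

#' Fisher-exact gene-set over-representation
#'
#' For each gene set, the 2x2 table is a = |DEGs in set|, b = |DEGs outside
#' set|, c = |set outside DEGs|, d = remaining background. The two-sided p
#' comes from the hypergeometric distribution; the odds ratio is the
#' cross-product ratio with a Haldane +0.5 correction (all cells) only when
#' some cell is zero, with a Wald 95% CI on the log odds ratio; p values
#' are BH-adjusted across sets. Sets are intersected with the background
#' before testing.
#'
#' @param deg_genes character vector of significant genes (must be a
#'   subset of `background`).
#' @param gene_sets named list of gene sets.
#' @param background character vector: the gene universe.
#' @return data.frame with one row per set: `set`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p`, `padj`.
#' @export
fisher_enrichment <- function(deg_genes, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  deg_genes <- unique(deg_genes)
  if (!all(deg_genes %in% background)) {
    stop("DEG genes must be contained in the background", call. = FALSE)
  }
  N <- length(background)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    a <- length(intersect(deg_genes, s))
    b <- length(deg_genes) - a
    cc <- length(s) - a
    d <- N - a - b - cc
    orci <- .odds_ratio_ci(a, b, cc, d)
    data.frame(set = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = orci[["or"]], ci_lo = orci[["lo"]],
               ci_hi = orci[["hi"]], p = .fisher_two_sided(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}

#' Overlap test between two gene lists against a fixed background
#'
#' Two-sided Fisher exact test of the overlap between two gene lists given
#' a fixed background size (30,000 protein-coding genes by default), with
#' the cross-product odds ratio and Wald 95% CI; an odds ratio below 1
#' indicates depletion, above 1 enrichment.
#'
#' @param list1,list2 character vectors of genes.
#' @param background_size fixed universe size.
#' @return one-row data.frame: contingency cells, `odds_ratio`, `ci_lo`,
#'   `ci_hi`, `p`, and `direction` ("enrichment" / "depletion" / "none").
#' @export
fixed_background_overlap <- function(list1, list2, background_size = 30000L) {
  list1 <- unique(list1)
  list2 <- unique(list2)
  if (length(union(list1, list2)) > background_size) {
    stop("lists exceed the background size", call. = FALSE)
  }
  a <- length(intersect(list1, list2))
  b <- length(list1) - a
  cc <- length(list2) - a
  d <- background_size - a - b - cc
  orci <- .odds_ratio_ci(a, b, cc, d)
  data.frame(a = a, b = b, c = cc, d = d,
             odds_ratio = orci[["or"]], ci_lo = orci[["lo"]],
             ci_hi = orci[["hi"]], p = .fisher_two_sided(a, b, cc, d),
             direction = if (orci[["or"]] > 1) "enrichment"
                         else if (orci[["or"]] < 1) "depletion" else "none",
             stringsAsFactors = FALSE)
}

#' Exclusive (UpSet) intersection counts
#'
#' Counts each element of the union in exactly one exclusive region (the
#' subset of input sets containing it), the quantity shown atop an UpSet
#' plot. Regions partition the union.
#'
#' @param sets named list of sets.
#' @return named integer vector; names are `&`-joined set names, in order
#'   of decreasing count.
#' @export
upset_exclusive_counts <- function(sets) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0L) return(stats::setNames(integer(0), character(0)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  tab <- sort(table(sig), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}
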