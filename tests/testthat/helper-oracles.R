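# Independent oracles used across the suite. These deliberately do NOT
# share code with the package implementation.

# Plain-R Smith-Waterman best local score (linear gaps), by exhaustive
# dynamic programming. Returns only the optimal score.
sw_score_oracle <- function(read, ref, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      h <- max(0, H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# Hand-rolled Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Exhaustive two-sided Fisher p for a 2x2 table from first principles:
# enumerate every table with the observed margins via binomial
# coefficients and sum the probabilities not exceeding the observed one.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  supp <- max(0, k - n):min(k, m)
  probs <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  min(1, sum(probs[probs <= probs[supp == a] * (1 + 1e-7)]))
}

# Random DNA string.
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small simulation configuration used where full scale is not needed.
tiny_config <- function(n_genes = 800L, ...) {
  sim_config(cells_per_sample = 25L, n_genes = n_genes,
             n_markers_per_type = 10L,
             module_spec = data.frame(size = rep(20L, 3L),
                                      cor = rep(0.6, 3L)),
             ...)
}

# Homogeneous-background configuration for co-expression recovery tests:
# one cell type, no markers, no planted DEGs, no mitochondrial genes, so
# genes outside the planted modules are uncorrelated.
module_config <- function(n_genes = 1000L, cells_per_sample = 125L,
                          module_spec = data.frame(size = rep(50L, 7L),
                                                   cor = rep(0.6, 7L)),
                          seed = 11L, ...) {
  sim_config(cells_per_sample = cells_per_sample, n_genes = n_genes,
             n_cell_types = 1L, n_markers_per_type = 0L,
             deg_spec = list(), n_mito_genes = 0L,
             module_spec = module_spec, module_trait_effect = NULL,
             qc_violation_rates = c(high_mito = 0), seed = seed, ...)
}
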