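# Signed network construction, module detection, eigengenes, rank scores,
# trait correlations.

test_that("the signed adjacency maps correlations through its endpoints", {
  # pooling_size 1 keeps the exact per-cell correlations
  np <- network_params(pooling_size = 1L, seed = 1L)
  x <- rnorm(50)
  y <- rnorm(50); y <- residuals(lm(y ~ x))  # exactly orthogonal
  m <- cbind(g1 = x, g2 = x, g3 = -x, g4 = y / sd(y))
  rownames(m) <- sprintf("c%02d", 1:50)
  a <- build_network(m, params = np)
  expect_equal(a["g1", "g2"], 1)               # r = 1
  expect_equal(a["g1", "g3"], 0)               # r = -1
  expect_equal(a["g1", "g4"], 0.5^8)           # r = 0, beta = 8
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(a, t(a))
  # invariance to cell order and gene order (up to label permutation)
  set.seed(2)
  pc <- sample(nrow(m)); pg <- sample(ncol(m))
  a2 <- build_network(m[pc, pg], params = np)
  expect_equal(a2[colnames(a), colnames(a)], a)
})

test_that("module detection recovers planted blocks and rejects noise", {
  # identity adjacency (all r = 0): everything grey
  id <- diag(40)
  dimnames(id) <- list(sprintf("g%02d", 1:40), sprintf("g%02d", 1:40))
  np <- network_params(min_module_size = 5L)
  expect_true(all(detect_modules(id, np) == "grey"))

  # two perfectly correlated blocks: exact membership
  set.seed(4)
  f1 <- rnorm(120); f2 <- rnorm(120)
  m <- cbind(matrix(f1, 120, 10), matrix(f2, 120, 10)) +
    matrix(rnorm(120 * 20, sd = 1e-3), 120)
  colnames(m) <- sprintf("g%02d", 1:20)
  rownames(m) <- sprintf("c%03d", 1:120)
  adj <- build_network(m, params = network_params(pooling_size = 1L,
                                                  min_module_size = 5L))
  mods <- detect_modules(adj, network_params(min_module_size = 5L))
  expect_identical(length(setdiff(unique(mods), "grey")), 2L)
  expect_identical(length(unique(mods[1:10])), 1L)
  expect_identical(length(unique(mods[11:20])), 1L)
  expect_false(mods[1] == mods[11])

  # planted 7-block generator at reduced scale: high agreement with truth
  cfg <- module_config(n_genes = 500L, cells_per_sample = 63L,
                       module_spec = data.frame(size = rep(30L, 7L),
                                                cor = rep(0.6, 7L)),
                       seed = 17L)
  tr <- simulate_truth(cfg)
  cnt <- simulate_counts(tr, cfg)
  norm <- normalize_log(cnt$counts)
  keep <- filter_network_genes(cnt$counts, 0.05)
  np2 <- network_params(pooling_size = 10L, min_module_size = 15L)
  adj2 <- build_network(norm[, keep], cnt$cell_meta$cell_type, np2)
  mods2 <- detect_modules(adj2, np2)
  expect_identical(length(setdiff(unique(mods2), "grey")), 7L)
  truth_mod <- cnt$module_truth$module[match(names(mods2),
                                             cnt$module_truth$gene)]
  ok <- !is.na(truth_mod)
  tab <- table(truth_mod[ok], mods2[ok])
  expect_gte(mean(apply(tab, 1, max) / rowSums(tab)), 0.9)
})

test_that("eigengenes are unit-norm, sign-aligned, and recover the latent
           activity", {
  set.seed(6)
  f <- rnorm(200)
  m <- matrix(f, 200, 5) + matrix(rnorm(1000, sd = 0.4), 200)
  colnames(m) <- sprintf("g%d", 1:5)
  eg <- module_eigengene(m, colnames(m))
  expect_equal(sum(eg$eigengene^2), 1)
  expect_true(all(eg$kme > 0.8))
  expect_gte(abs(cor(eg$eigengene, f)), 0.9)
  # flipping the module's data flips the eigengene
  eg2 <- module_eigengene(-m, colnames(m))
  expect_equal(eg2$eigengene, -eg$eigengene, tolerance = 1e-8)
  # identical genes: variance fully explained, kme 1
  ident <- matrix(f, 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  eg3 <- module_eigengene(ident, c("a", "b", "c"))
  expect_equal(eg3$var_explained, 1)
  expect_equal(unname(eg3$kme), rep(1, 3), tolerance = 1e-8)
  # single-gene module: the gene's scaled profile
  eg4 <- module_eigengene(m, "g1")
  expect_equal(abs(cor(eg4$eigengene, m[, "g1"])), 1)
  expect_error(module_eigengene(m, character(0)), "empty")

  hubs <- kme_hubs(m, setNames(rep("M1", 5), colnames(m)), n_hubs = 3L)
  expect_identical(nrow(hubs), 3L)
  expect_true(all(diff(hubs$kme) <= 0))
})

test_that("the rank module score hits its endpoints and is rank-based", {
  G <- 100L
  expr <- setNames(seq(G, 1), sprintf("g%03d", 1:G))  # g001 highest
  # module at the top ranks: score 1
  expect_equal(rank_module_score(expr, sprintf("g%03d", 1:10), max_rank = 50),
               1)
  # module at/beyond the ceiling: score 0
  expect_equal(rank_module_score(expr, sprintf("g%03d", 51:60), max_rank = 50),
               0)
  expect_error(rank_module_score(expr, names(expr)[1:60], max_rank = 50),
               "max_rank")
  # invariant to monotone transforms
  mod <- sprintf("g%03d", c(5, 20, 77))
  s1 <- rank_module_score(expr, mod, max_rank = 80)
  s2 <- rank_module_score(exp(expr / 10), mod, max_rank = 80)
  expect_equal(s1, s2)
  # random cells average 0.5
  set.seed(8)
  sc <- replicate(1000, {
    e <- setNames(sample(G), names(expr))
    rank_module_score(e, mod, max_rank = G)
  })
  expect_lt(abs(mean(sc) - 0.5), 0.03)
})

test_that("module-trait correlations detect the planted trait and stay
           calibrated", {
  set.seed(10)
  n <- 200
  trt <- rep(0:1, each = n / 2)
  e <- cbind(M1 = trt, M2 = rnorm(n), M3 = rnorm(n))
  traits <- cbind(treatment = trt, genotype = rbinom(n, 1, 0.5))
  mt <- module_trait_correlation(e, traits)
  expect_equal(mt$r[mt$module == "M1" & mt$trait == "treatment"], 1)
  # orthogonal-by-construction pair has r = 0
  x <- rnorm(n)
  y <- residuals(lm(rnorm(n) ~ x))
  mt2 <- module_trait_correlation(cbind(M = x), cbind(t1 = y))
  expect_lt(abs(mt2$r), 1e-10)
  # constant trait reported missing
  mt3 <- module_trait_correlation(cbind(M = x), cbind(k = rep(1, n)))
  expect_true(is.na(mt3$r) && is.na(mt3$padj))

  # calibration over 100 simulated runs: the planted pair is detected,
  # null pairs stay at the nominal false-discovery level
  hits <- 0L; null_sig <- 0L; null_tot <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    eg <- cbind(M1 = trt + rnorm(n), M2 = rnorm(n), M3 = rnorm(n))
    tra <- cbind(treatment = trt, genotype = rbinom(n, 1, 0.5))
    res <- module_trait_correlation(eg, tra)
    planted <- res$module == "M1" & res$trait == "treatment"
    hits <- hits + (res$padj[planted] <= 0.05)
    null_sig <- null_sig + sum(res$padj[!planted] <= 0.05, na.rm = TRUE)
    null_tot <- null_tot + sum(!planted)
  }
  expect_gte(hits, 95L)
  expect_lte(null_sig / null_tot, 0.05)
})

test_that("module-marker overlap flags identical sets and ignores
           disjoint ones", {
  genes <- sprintf("g%03d", 1:200)
  assign <- setNames(rep("grey", 200), genes)
  assign[1:30] <- "M1"; assign[31:60] <- "M2"
  markers <- list(typeA = genes[1:30], typeB = genes[101:120])
  ov <- module_marker_overlap(assign, markers)
  identical_case <- ov[ov$module == "M1" & ov$set == "typeA", ]
  expect_identical(identical_case$a, 30L)
  expect_lt(identical_case$p, 1e-10)
  disjoint <- ov[ov$module == "M2" & ov$set == "typeB", ]
  expect_identical(disjoint$a, 0L)
  expect_lt(disjoint$odds_ratio, 1)
})
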