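test_that("PAV distances match hand computation on a toy matrix", {
  m <- pav_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
                  gene_ids = paste0("g", 1:3),
                  accession_ids = paste0("a", 1:3))
  d_sm <- pav_distance(m, "simple_matching")
  # a1 vs a2: rows differ at g2 and g3 -> 2/3.
  expect_equal(d_sm["a1", "a2"], 2 / 3)
  expect_equal(d_sm["a1", "a3"], 2 / 3)
  expect_equal(d_sm["a2", "a3"], 2 / 3)

  d_j <- pav_distance(m, "jaccard")
  # a1 present {g1,g2}, a2 present {g1,g3}: |int| 1, |union| 3.
  expect_equal(d_j["a1", "a2"], 1 - 1 / 3)

  same <- pav_matrix(cbind(c(1L, 0L, 1L), c(1L, 0L, 1L)))
  expect_true(all(pav_distance(same) == 0))

  compl <- pav_matrix(cbind(c(1L, 0L, 1L), c(0L, 1L, 0L)))
  expect_equal(pav_distance(compl)[1, 2], 1)
})

test_that("simple matching is a metric on random matrices", {
  for (seed in 1:5) {
    m <- random_pav(30, 6, p = 0.5, seed = seed)
    d <- pav_distance(m)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    n <- ncol(m)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("PCA is centered, deterministic in sign, and matches eigen", {
  m <- random_pav(40, 8, p = 0.5, seed = 77)
  p <- pav_pca(m, n_components = 3)
  x <- scale(t(unclass(m)), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(p$explained$variance, ev[1:3], tolerance = 1e-9)

  dup <- pav_matrix(cbind(unclass(m)[, 1], unclass(m)[, 1], unclass(m)[, 2]),
                    accession_ids = c("x1", "x2", "y"))
  pd <- pav_pca(dup, 1)
  expect_equal(pd$scores$PC1[1], pd$scores$PC1[2], tolerance = 1e-12)

  # Two clades with disjoint variable genes separate along PC1.
  block <- rbind(matrix(1L, 10, 8),
                 cbind(matrix(1L, 6, 4), matrix(0L, 6, 4)),
                 cbind(matrix(0L, 6, 4), matrix(1L, 6, 4)))
  pb <- pav_pca(pav_matrix(block), 1)
  s <- pb$scores$PC1
  expect_true(all(sign(s[1:4]) == sign(s[1])))
  expect_true(all(sign(s[5:8]) == -sign(s[1])))
})

test_that("rank deficits truncate components with a warning", {
  m <- pav_matrix(cbind(c(1L, 0L), c(0L, 1L), c(1L, 0L)))
  expect_warning(p <- pav_pca(m, n_components = 3), "rank")
  expect_lte(nrow(p$explained), 2)
})

test_that("3-taxon NJ solves the pairwise equations exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("NJ recovers additive 4- and 5-taxon metrics exactly", {
  for (seed in c(3, 9)) {
    for (ntaxa in 4:5) {
      set.seed(seed)
      true_tree <- ape::rtree(ntaxa, br = function(n) runif(n, 0.5, 2))
      d <- ape::cophenetic.phylo(true_tree)
      ord <- sort(rownames(d))
      d <- d[ord, ord]
      tr <- nj_tree(d)
      pd <- ape::cophenetic.phylo(tr)[ord, ord]
      expect_equal(pd, d, tolerance = 1e-9)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), tr)), 0)
    }
  }
})

test_that("NJ clamps negative branch lengths to zero", {
  # A strongly non-additive metric known to produce negative NJ branches.
  d <- matrix(c(0, 1, 10, 10,
                1, 0, 10, 10,
                10, 10, 0, 0.1,
                10, 10, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(as.dist(d))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})

test_that("the NJ tree separates simulated clades at its basal split", {
  sim <- simulate_pangenome(sim_config(
    n_accessions = 30, n_genes = 400, frac_hardcore = 0.5, frac_softcore = 0,
    frac_shell = 0.5, frac_cloud = 0, clade_bias = 0.5,
    clade_informative_frac = 0.8, seed = 55))
  d <- pav_distance(sim$truth_matrix)
  split <- tree_bipartition(nj_tree(d))
  joined <- dplyr::left_join(split, sim$clades, by = "accession_id")
  agree <- mean(joined$clade.x == joined$clade.y)
  expect_true(agree == 1 || agree == 0)  # labels I/II may swap sides
})

test_that("Mantel statistic and p-value behave at the extremes", {
  d <- pav_distance(random_pav(50, 10, p = 0.5, seed = 21))
  mt <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(mt$statistic, 1.0)
  expect_equal(mt$p_value, 1 / 100)

  const <- matrix(1, 5, 5); diag(const) <- 0
  expect_error(mantel_test(const, const, n_perm = 9), "Constant")
})

test_that("exact Mantel p equals enumeration over all 24 permutations", {
  set.seed(31)
  for (rep in 1:3) {
    a <- matrix(runif(16), 4); d1 <- (a + t(a)) / 2; diag(d1) <- 0
    b <- matrix(runif(16), 4); d2 <- (b + t(b)) / 2; diag(d2) <- 0
    mt <- mantel_test(d1, d2, exact = TRUE)
    # Independent enumeration oracle.
    off <- upper.tri(d1)
    perms <- expand.grid(1:4, 1:4, 1:4, 1:4)
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
    r_obs <- cor(d1[off], d2[off])
    r_all <- apply(perms, 1, function(p) {
      p <- as.integer(p)
      cor(d1[off], d2[p, p][off])
    })
    expect_equal(mt$n_perm, 24L)
    expect_equal(mt$p_value, mean(r_all >= r_obs - 1e-12))
  }
})

test_that("Mantel is invariant to joint relabeling and matches vegan", {
  skip_if_not_installed("vegan")
  d1 <- pav_distance(random_pav(60, 12, p = 0.5, seed = 5))
  d2 <- simulate_snp_distance(pav_matrix(unclass(random_pav(60, 12, p = 0.5,
                                                            seed = 6))),
                              mixing = 0.5, seed = 7)
  dimnames(d2) <- dimnames(d1)
  mt <- mantel_test(d1, d2, n_perm = 99, seed = 2)
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(mt$statistic, unname(vg$statistic), tolerance = 1e-12)

  p <- sample(1:12)
  mt_rel <- mantel_test(d1[p, p], d2[p, p], n_perm = 99, seed = 2)
  expect_equal(mt_rel$statistic, mt$statistic, tolerance = 1e-12)
})

test_that("Welch t matches the textbook formula and degenerate cases", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p_value, 2 * pt(t_hand, df_hand))

  same <- welch_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("clade gene-loss contrast detects simulated clade bias", {
  sim <- simulate_pangenome(sim_config(
    n_accessions = 40, n_genes = 500, frac_hardcore = 0.4, frac_softcore = 0,
    frac_shell = 0.6, frac_cloud = 0, clade_bias = 0.4,
    clade_informative_frac = 0.7, seed = 66))
  res <- clade_gene_loss(sim$truth_matrix, clades = sim$clades)
  # Clade I carries the extra absence.
  expect_gt(res$test$estimate_a, res$test$estimate_b)
  expect_lt(res$test$p_value, 0.01)
})
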