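# PCA, IBS distances, neighbor-joining.

test_that("identical samples get identical PC coordinates", {
  calls <- rbind(
    c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 0L, 0L, 1L),
    c(1L, 2L, 1L, 0L)
  )
  g <- gm(calls)
  res <- pca_genotypes(g, n_components = 2)
  expect_equal(
    res$coordinates[1, ], res$coordinates[2, ],
    tolerance = 1e-8
  )
})

test_that("variance explained is consistent with coordinate variances", {
  g <- random_gm(20, 200, miss = 0.05, seed = 77)
  res <- suppressMessages(pca_genotypes(g, n_components = 5))
  ve <- res$variance_explained
  expect_true(all(ve >= 0 & ve <= 1))
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-9)
  cv <- apply(res$coordinates, 2, stats::var)
  expect_equal(
    cv / cv[1], ve[1:5] / ve[1],
    tolerance = 1e-8, ignore_attr = TRUE
  )
})

test_that("PCA is centering-invariant and allele-flip invariant", {
  set.seed(12)
  calls <- matrix(sample(0:1, 60, replace = TRUE), nrow = 6)
  g <- gm(calls)
  shifted <- calls
  shifted[, 3] <- shifted[, 3] + 1L # 0/1 -> 1/2: pure translation
  g2 <- gm(shifted)
  a <- pca_genotypes(g, n_components = 3, scaling = "none")
  b <- pca_genotypes(g2, n_components = 3, scaling = "none")
  expect_equal(abs(a$coordinates), abs(b$coordinates), tolerance = 1e-9)

  flipped <- calls
  flipped[, 5] <- 2L - flipped[, 5] # allele relabel
  g3 <- gm(flipped)
  c3 <- pca_genotypes(g3, n_components = 3, scaling = "none")
  expect_equal(abs(a$coordinates), abs(c3$coordinates), tolerance = 1e-9)
})

test_that("PC1 separates two drifted populations with no sign overlap", {
  sim <- simulate_genotypes(sim_params(
    n_pop1 = 30, n_pop2 = 30, n_chrom = 1, chrom_len = 5e6,
    snp_density = 1e-3, f_background = 0.1,
    sweeps = data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      swept_pop = character(), stringsAsFactors = FALSE
    ),
    seed = 21
  ))
  g <- sim$genotypes
  res <- suppressMessages(pca_genotypes(g, n_components = 2))
  pc1 <- res$coordinates[, 1]
  s1 <- sign(pc1[g$samples$population == "highland"])
  s2 <- sign(pc1[g$samples$population == "lowland"])
  expect_true(all(s1 == s1[1]))
  expect_true(all(s2 == s2[1]))
  expect_true(s1[1] != s2[1])
})

test_that("IBS distance follows its definition", {
  g <- gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(unname(ibs_distance(g)[1, 2]), 0)

  g2 <- gm(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L)))
  expect_equal(unname(ibs_distance(g2)[1, 2]), 1)

  g3 <- gm(rbind(c(0L, 1L, 2L), c(0L, 2L, 2L)))
  expect_equal(unname(ibs_distance(g3)[1, 2]), 1 - 5 / 6)
})

test_that("IBS matches the brute-force oracle and is metric on fixtures", {
  g <- random_gm(8, 60, miss = 0.2, seed = 5)
  d <- ibs_distance(g)
  expect_equal(d, oracle_ibs(g), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  n <- nrow(d)
  for (i in 1:n) {
    for (j in 1:n) {
      for (k in 1:n) {
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
      }
    }
  }
})

test_that("a pair with no jointly called variants is a named error", {
  calls <- rbind(c(0L, NA), c(NA, 2L))
  g <- gm(calls)
  expect_error(ibs_distance(g), "s01.*s02")
})

test_that("NJ recovers an additive 4-taxon tree exactly", {
  d <- additive_matrix_4taxa(2, 3, 1.5, 4, 5)
  tree <- nj_tree(d)
  expect_s3_class(tree, "phylo")
  expect_false(ape::is.rooted(tree))
  cd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-9)
  # the generating split t1t2 | t3t4 must be present
  expect_equal(sort(tree$edge.length), sort(c(2, 3, 1.5, 4, 5)),
    tolerance = 1e-9
  )
})

test_that("3-taxon NJ solves the three-point formulas", {
  d <- matrix(
    c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tree <- nj_tree(d)
  # x = (dab + dac - dbc)/2 etc.
  want <- c(a = 2, b = 3, c = 7)
  tips <- tree$tip.label[tree$edge[, 2] <= 3]
  got <- stats::setNames(
    tree$edge.length[tree$edge[, 2] <= 3],
    tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]]
  )
  expect_equal(got[names(want)], want, tolerance = 1e-9)
})

test_that("NJ is invariant to input label permutation", {
  set.seed(31)
  ref <- ape::rtree(8)
  d <- ape::cophenetic.phylo(ref)
  t1 <- nj_tree(d)
  perm <- sample(rownames(d))
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  c1 <- ape::cophenetic.phylo(t1)
  c2 <- ape::cophenetic.phylo(t2)[rownames(c1), colnames(c1)]
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("NJ validates its input", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(d), "at least 3")
  bad <- matrix(c(0, 1, 2, 1, 0, 1, 2.5, 1, 0), 3, 3,
    dimnames = list(letters[1:3], letters[1:3])
  )
  expect_error(nj_tree(bad), "symmetric")
  neg <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3,
    dimnames = list(letters[1:3], letters[1:3])
  )
  expect_error(nj_tree(neg), "non-negative")
})
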