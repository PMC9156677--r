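test_that("alpha diversity matches hand-computed values", {
  tbl <- tibble::tibble(sample_id = c("a", "b", "c"),
                        s1 = c(1, 1, 2), s2 = c(0, 1, 1), s3 = c(0, 1, 1),
                        s4 = c(0, 1, 0))
  out <- alpha_diversity(tbl)
  expect_equal(out$richness, c(1L, 4L, 3L))
  expect_equal(out$shannon[1], 0)
  expect_equal(out$shannon[2], log(4))
  expect_equal(out$shannon[3],
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
})

test_that("Shannon ignores species order and zero-abundance species", {
  set.seed(4)
  m <- matrix(rpois(5 * 8, 4), 5, 8, dimnames = list(NULL, paste0("s", 1:8)))
  h1 <- alpha_diversity(m)$shannon
  h2 <- alpha_diversity(m[, sample(8)])$shannon
  expect_equal(h1, h2)
  h3 <- alpha_diversity(cbind(m, ghost = 0))$shannon
  expect_equal(h1, h3)
})

test_that("Bray-Curtis matches its closed form", {
  m <- rbind(a = c(2, 1), b = c(1, 1), c = c(1, 0), d = c(0, 1))
  colnames(m) <- c("x", "y")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "a"], 0)
  expect_equal(d["c", "d"], 1)       # disjoint support
  expect_equal(d["a", "b"], 0.2)     # (1+0)/(3+2)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA reproduces Euclidean geometry", {
  # equilateral triangle: two equal positive axes, third trivial
  d3 <- as.dist(matrix(1, 3, 3) - diag(3))
  ord <- pcoa(d3)
  expect_equal(ord$eigenvalues[1], ord$eigenvalues[2], tolerance = 1e-10)
  expect_lt(abs(ord$eigenvalues[3]), 1e-10)
  expect_equal(ord$prop_explained[1:2], c(0.5, 0.5), tolerance = 1e-10)

  # planar points: distances reconstructed from coordinates
  set.seed(11)
  pts <- matrix(rnorm(2 * 12), 12, 2)
  d <- dist(pts)
  ord2 <- pcoa(d)
  coords <- as.matrix(ord2$coordinates[, -1])
  expect_equal(as.vector(dist(coords)), as.vector(d), tolerance = 1e-8)

  # collinear points: all variance on axis 1
  ord3 <- pcoa(dist(matrix(c(0, 1, 2.5, 4), 4, 1)))
  expect_equal(ord3$prop_explained[1], 1, tolerance = 1e-10)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA eigenvalues agree with an independent implementation", {
  skip_if_not_installed("ape")
  z <- latent_block_table(n = 12, n_species = 8, seed = 21)
  d <- bray_curtis(z - min(z) + 0.01)
  ours <- pcoa(d)$eigenvalues
  theirs <- ape::pcoa(d)$values$Eigenvalues
  expect_equal(ours[seq_along(theirs)], theirs, tolerance = 1e-8)
})

test_that("PERMANOVA pseudo-F matches vegan and detects separation", {
  skip_if_not_installed("vegan")
  z <- latent_block_table(n = 16, n_species = 10, seed = 8)
  groups <- rep(c("A", "B"), each = 8)
  d <- bray_curtis(z - min(z) + 0.01)
  ours <- permanova(d, groups, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                        permutations = 99)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)

  # strong separation saturates the permutation p at 1/(n_perm + 1);
  # groups large enough that no sampled relabeling recreates the split
  set.seed(14)
  sep <- matrix(rnorm(24 * 6), 24, 6)
  sep[13:24, ] <- sep[13:24, ] + 50
  strong <- permanova(dist(sep), rep(c("A", "B"), each = 12),
                      n_perm = 999, seed = 2)
  expect_equal(strong$p_value, 0.001)

  expect_error(permanova(d, c(rep("A", 15), "B"), n_perm = 9), "2 samples")
})

test_that("ANOSIM matches vegan, is rank-invariant, and saturates at R = 1", {
  skip_if_not_installed("vegan")
  z <- latent_block_table(n = 14, n_species = 10, seed = 12)
  groups <- rep(c("A", "B"), each = 7)
  d <- dist(z)
  ours <- anosim(d, groups, n_perm = 99, seed = 3)
  ref <- suppressWarnings(vegan::anosim(d, groups, permutations = 9))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)

  # rank-based: squaring the distances changes nothing
  sq <- anosim(d^2, groups, n_perm = 99, seed = 3)
  expect_equal(ours$statistic, sq$statistic)
  expect_equal(ours$p_value, sq$p_value)

  sep <- z; sep[8:14, ] <- sep[8:14, ] + 100
  expect_equal(anosim(dist(sep), groups, n_perm = 99, seed = 1)$statistic, 1)
})

test_that("permutation tests are reproducible under a fixed seed", {
  z <- latent_block_table(n = 12, n_species = 6, seed = 30)
  groups <- rep(c("A", "B"), each = 6)
  d <- dist(z)
  expect_identical(permanova(d, groups, n_perm = 199, seed = 5),
                   permanova(d, groups, n_perm = 199, seed = 5))
  expect_identical(anosim(d, groups, n_perm = 199, seed = 5),
                   anosim(d, groups, n_perm = 199, seed = 5))
})

test_that("cluster concordance tests the 2x2 cluster-cohort table", {
  # perfectly separated cohorts: clusters coincide, Fisher p = 2/252
  set.seed(6)
  m <- rbind(matrix(rnorm(5 * 4), 5, 4), matrix(rnorm(5 * 4, 20), 5, 4))
  rownames(m) <- sprintf("s%02d", 1:10); colnames(m) <- paste0("f", 1:4)
  groups <- rep(c("A", "B"), each = 5)
  res <- cluster_concordance(dist(m), groups)
  expect_s3_class(res$dendrogram, "hclust")
  expect_equal(res$test$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_lt(res$test$p_value, 0.01)

  # three cohorts: dendrogram returned, test skipped with a warning
  expect_warning(res3 <- cluster_concordance(dist(m), rep(c("A", "B", "C"),
                                                          c(4, 3, 3))),
                 "2 cohorts")
  expect_null(res3$test)
})

test_that("Fisher's exact two-sided p matches enumeration on balanced tables", {
  expect_equal(fisher.test(matrix(c(3, 3, 3, 3), 2))$p.value, 1)
  expect_equal(fisher_enum_p(3, 3, 3, 3), 1)
})
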