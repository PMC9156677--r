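test_that("LOO-averaged p behaves at the degenerate and null extremes", {
  x <- cbind(a = 1:10 + 0, b = 2 * (1:10) + 3)
  res <- loo_averaged_correlation(x, "a", "b")
  expect_equal(res$r, 1)
  expect_lt(res$p_avg, 1e-6)

  # mean of the jackknife p-values sits between their extremes
  set.seed(7)
  m <- cbind(a = rnorm(12), b = rnorm(12))
  ps <- vapply(1:12, function(k) {
    cor.test(m[-k, 1], m[-k, 2])$p.value
  }, numeric(1))
  got <- loo_averaged_correlation(m, "a", "b")$p_avg
  expect_gte(got, min(ps) - 1e-12)
  expect_lte(got, max(ps) + 1e-12)
  expect_equal(got, mean(ps), tolerance = 1e-10)

  # null pairs: averaged p is roughly uniform
  set.seed(8)
  pbar <- mean(vapply(1:200, function(i) {
    loo_averaged_correlation(matrix(rnorm(20), 10, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             "a", "b")$p_avg
  }, numeric(1)))
  expect_lt(abs(pbar - 0.5), 0.06)
})

test_that("two-stage BH matches hand-executed steps and controls FDR", {
  all_small <- two_stage_bh(rep(0.001, 10), q_level = 0.10)
  expect_true(all(all_small$rejected))

  hand <- two_stage_bh(c(0.001, 0.2, 0.9), q_level = 0.10)
  expect_equal(hand$rejected, c(TRUE, FALSE, FALSE))
  expect_true(all(hand$q >= hand$p))

  expect_equal(nrow(two_stage_bh(numeric(0))), 0)
  expect_error(two_stage_bh(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("two-stage BH agrees with an independent step-up implementation", {
  tst_ref <- function(p, q) {
    m <- length(p); qp <- q / (1 + q)
    step_up <- function(p, alpha) {
      o <- order(p); ps <- p[o]
      k <- which(ps <= alpha * seq_len(m) / m)
      rej <- logical(m)
      if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
      rej
    }
    r1 <- sum(step_up(p, qp))
    m0 <- m - r1
    if (m0 == 0) return(rep(TRUE, m))
    step_up(p, qp * m / m0)
  }
  set.seed(9)
  for (i in 1:25) {
    p <- runif(40)^sample(c(1, 2, 3), 1)  # varying signal density
    expect_equal(two_stage_bh(p, 0.10)$rejected, tst_ref(p, 0.10))
  }
})

test_that("network construction recovers planted blocks and prunes honestly", {
  recovered <- vapply(1:30, function(s) {
    z <- latent_block_table(seed = 400 + s)
    net <- suppressWarnings(
      build_network(gaussianize(z), rep(c("SE", "EE"), each = 10)))
    ed <- net$edges
    blk <- function(x) {
      i <- as.integer(sub("sp", "", x))
      ifelse(i <= 7, 1L, ifelse(i <= 14, 2L, 0L))
    }
    within <- blk(ed$from) > 0 & blk(ed$from) == blk(ed$to) & ed$r > 0
    sum(within) / 42
  }, numeric(1))
  expect_gte(mean(recovered), 0.8)

  z <- latent_block_table(seed = 5)
  net <- suppressWarnings(
    build_network(gaussianize(z), rep(c("SE", "EE"), each = 10)))
  expect_true(all(net$edges$q >= net$edges$p))
  expect_true(all(net$edges$thickness %in% 1:8))
  # thickness inversely monotone in q
  ord <- order(net$edges$q)
  expect_false(is.unsorted(rev(net$edges$thickness[ord])))
  expect_equal(net$nodes$degree,
               vapply(net$nodes$species, function(sp) {
                 sum(net$edges$from == sp | net$edges$to == sp)
               }, integer(1), USE.NAMES = FALSE))
})

test_that("null networks keep the false-edge proportion near the FDR level", {
  set.seed(10)
  fdp <- vapply(1:60, function(s) {
    sim <- simulate_null_study(simulation_params(n_species = 15), seed = 600 + s)
    norm <- gaussianize(prevalence_filter(
      to_relative_abundance(sim$study$abundance), 0.05))
    net <- suppressWarnings(
      build_network(norm, cohort_labels(sim$study)))
    # every surviving edge on null data is false
    nrow(net$edges) / choose(ncol(norm) - 1, 2)
  }, numeric(1))
  expect_lte(mean(fdp), 0.10)
})

test_that("consensus SIG detection is exact on disjoint cliques", {
  nodes <- tibble::tibble(
    species = letters[1:6], affinity = rep(c("EE", "SE"), each = 3),
    prevalence = 1, degree = NA_integer_, betweenness = NA_real_,
    keystonness = NA_real_, sig = NA_integer_)
  cl <- t(combn(1:3, 2))
  edges <- tibble::tibble(
    from = letters[c(cl[, 1], cl[, 1] + 3)],
    to = letters[c(cl[, 2], cl[, 2] + 3)],
    r = 0.9, p = 0.001, q = 0.002, sign = "positive", thickness = 8L)
  net <- structure(list(nodes = nodes, edges = edges, partition = NULL),
                   class = "sig_network")
  out <- consensus_sigs(net, iterations = 50, seed = 1)
  memb <- out$partition$membership
  expect_equal(length(unique(memb$sig)), 2)
  expect_equal(memb$sig[1:3], rep(memb$sig[1], 3))
  expect_equal(memb$sig[4:6], rep(memb$sig[4], 3))
  expect_equal(memb$stability, rep(1, 6))
  # determinism
  out2 <- consensus_sigs(net, iterations = 50, seed = 1)
  expect_identical(out$partition$membership, out2$partition$membership)
})

test_that("consensus partition is equivariant under node relabeling", {
  z <- latent_block_table(seed = 77)
  groups <- rep(c("SE", "EE"), each = 10)
  net <- suppressWarnings(build_network(gaussianize(z), groups))
  out <- consensus_sigs(net, iterations = 60, seed = 4)

  perm <- sample(ncol(z))
  z2 <- z[, perm]
  net2 <- suppressWarnings(build_network(gaussianize(z2), groups))
  out2 <- consensus_sigs(net2, iterations = 60, seed = 4)

  m1 <- out$partition$membership
  m2 <- out2$partition$membership
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(
    m1$sig[match(sort(m1$species), m1$species)],
    m2$sig[match(sort(m2$species), m2$species)])
  expect_gt(ari, 0.99)
})

test_that("centralities match closed forms on canonical graphs", {
  path3 <- structure(list(
    nodes = tibble::tibble(species = c("a", "b", "c"), affinity = "EE",
                           prevalence = 1, degree = NA_integer_,
                           betweenness = NA_real_, keystonness = NA_real_,
                           sig = NA_integer_),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                           r = 0.5, p = 0.01, q = 0.02,
                           sign = "positive", thickness = 4L),
    partition = NULL), class = "sig_network")
  out <- node_centralities(path3)
  expect_equal(out$nodes$betweenness, c(0, 1, 0))
  expect_equal(out$nodes$keystonness, out$nodes$betweenness)

  star <- structure(list(
    nodes = tibble::tibble(species = c("hub", paste0("l", 1:4)),
                           affinity = "EE", prevalence = 1,
                           degree = NA_integer_, betweenness = NA_real_,
                           keystonness = NA_real_, sig = NA_integer_),
    edges = tibble::tibble(from = "hub", to = paste0("l", 1:4),
                           r = 0.5, p = 0.01, q = 0.02,
                           sign = "positive", thickness = 4L),
    partition = NULL), class = "sig_network")
  out2 <- node_centralities(star)
  expect_equal(out2$nodes$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(out2$nodes$betweenness, c(1, 0, 0, 0, 0))
})

test_that("betweenness matches the brute-force oracle on random graphs", {
  set.seed(13)
  for (trial in 1:25) {
    n <- sample(4:7, 1)
    adj <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- rbinom(1, 1, 0.5)
    }
    if (sum(adj) == 0) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    got <- igraph::betweenness(g, directed = FALSE, weights = NA,
                               normalized = TRUE)
    want <- betweenness_brute(adj)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("SIG-cohort opposition reduces to the exact hypergeometric", {
  nodes <- tibble::tibble(
    species = sprintf("s%02d", 1:14),
    affinity = rep(c("EE", "SE"), each = 7),
    prevalence = 1, degree = 0L, betweenness = 0, keystonness = 0,
    sig = rep(1:2, each = 7))
  net <- structure(list(
    nodes = nodes,
    edges = tibble::tibble(from = character(), to = character(),
                           r = numeric(), p = numeric(), q = numeric(),
                           sign = character(), thickness = integer()),
    partition = list(membership = tibble::tibble(
      species = nodes$species, sig = nodes$sig, stability = 1))),
    class = "sig_network")
  res <- sig_cohort_fisher(net, 1, 2)
  expect_equal(res$p_value, 2 / choose(14, 7), tolerance = 1e-12)
  expect_equal(res$p_value, fisher_enum_p(7, 0, 0, 7), tolerance = 1e-12)

  balanced <- net
  balanced$nodes$affinity <- rep(c("EE", "SE"), 7)
  res2 <- sig_cohort_fisher(balanced, 1, 2)
  expect_equal(res2$p_value, 1)
})
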