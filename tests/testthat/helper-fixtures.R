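# Small in-code fixtures shared across test files.

tiny_abundance <- function() {
  tibble::tibble(sample_id = c("m1", "m2", "m3"),
                 sp1 = c(2, 0, 1), sp2 = c(2, 3, 1), sp3 = c(4, 3, 2))
}

tiny_metadata <- function() {
  tibble::tibble(sample_id = c("m1", "m2", "m3"),
                 cohort = c("SE", "SE", "EE"))
}

tiny_study <- function() {
  cohort_study(tiny_abundance(), tiny_metadata())
}

# latent two-block Gaussian table: 7+7 block species + noise species
latent_block_table <- function(n = 20, n_species = 30, rho = 0.8,
                               seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n_species), n, n_species)
  if (n_species >= 14) {
    f <- matrix(rnorm(n * 2), n, 2)
    for (j in 1:7)  z[, j] <- sqrt(rho) * f[, 1] + sqrt(1 - rho) * z[, j]
    for (j in 8:14) z[, j] <- sqrt(rho) * f[, 2] + sqrt(1 - rho) * z[, j]
  }
  dimnames(z) <- list(sprintf("m%02d", seq_len(n)),
                      sprintf("sp%03d", seq_len(n_species)))
  z
}

block_truth <- function() rep(1:2, each = 7)

# a small deterministic network for export tests
toy_network <- function() {
  nodes <- tibble::tibble(
    species = c("A", "B", "C"),
    affinity = c("EE", "EE", "SE"),
    prevalence = c(1, 0.9, 0.8),
    degree = c(1L, 2L, 1L), betweenness = c(0, 1, 0),
    keystonness = c(0, 1, 0), sig = c(1L, 1L, 2L)
  )
  edges <- tibble::tibble(
    from = c("A", "B"), to = c("B", "C"),
    r = c(0.9, -0.7), p = c(0.001, 0.01), q = c(0.005, 0.03),
    sign = c("positive", "negative"), thickness = c(8L, 4L)
  )
  structure(list(nodes = nodes, edges = edges, partition = NULL),
            class = "sig_network")
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force normalized betweenness via BFS shortest-path counting
betweenness_brute <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in 1:n) for (t in 1:n) {
    if (s >= t) next
    # BFS from s: distances and path counts
    dist <- rep(Inf, n); cnt <- rep(0, n)
    dist[s] <- 0; cnt[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
      }
      frontier <- unique(nxt)
    }
    if (is.infinite(dist[t]) || cnt[t] == 0) next
    # count s-t shortest paths through each interior v
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (dist[v] + bfs_dist(adj, v)[t] == dist[t]) {
        # paths through v = cnt(s->v) * cnt(v->t)
        cv <- bfs_cnt(adj, v)
        btw[v] <- btw[v] + cnt[v] * cv[t] / cnt[t]
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

bfs_dist <- function(adj, s) {
  n <- nrow(adj); dist <- rep(Inf, n); dist[s] <- 0; frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) for (w in which(adj[v, ] > 0)) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
    }
    frontier <- unique(nxt)
  }
  dist
}

bfs_cnt <- function(adj, s) {
  n <- nrow(adj); dist <- rep(Inf, n); cnt <- rep(0, n)
  dist[s] <- 0; cnt[s] <- 1; frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) for (w in which(adj[v, ] > 0)) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
    }
    frontier <- unique(nxt)
  }
  cnt
}
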