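#' Per-sample alpha diversity
#'
#' Richness is the count of species with positive abundance; the Shannon
#' index is \eqn{H = -\sum p_i \log p_i} in nats over the sample's nonzero
#' proportions, so \eqn{0 \le H \le \log S} with equality at uniformity.
#'
#' @param abundance data frame with `sample_id` plus species columns, or a
#'   matrix; counts or relative abundances.
#' @param base logarithm base for Shannon (default `exp(1)`, nats).
#' @return tibble with columns `sample_id`, `richness`, `shannon`.
#' @examples
#' alpha_diversity(tibble::tibble(sample_id = c("a", "b"),
#'                                sp1 = c(1, 1), sp2 = c(0, 1)))
#' @export
alpha_diversity <- function(abundance, base = exp(1)) {
  m <- as_feature_matrix(abundance)
  rs <- rowSums(m)
  if (any(rs <= 0)) abort("Samples with zero total abundance.")
  p <- m / rs
  tibble::tibble(
    sample_id = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = unname(apply(p, 1, function(pi) {
      pi <- pi[pi > 0]
      -sum(pi * log(pi, base = base))
    }))
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' `[0, 1]`, computed through [vegan::vegdist()].
#'
#' @param abundance data frame with `sample_id` plus species columns, or a
#'   matrix; at least 2 samples, nonnegative values.
#' @return a [stats::dist] object labelled by sample id.
#' @export
bray_curtis <- function(abundance) {
  m <- as_feature_matrix(abundance)
  if (nrow(m) < 2) abort("Need at least 2 samples.")
  if (any(m < 0)) abort("Negative abundances.")
  if (any(rowSums(m) == 0)) {
    abort(paste0("Bray-Curtis undefined for all-zero sample(s): ",
                 toString(head(rownames(m)[rowSums(m) == 0], 5))))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of \eqn{-d^2/2},
#' eigendecomposition, coordinates scaled by the square root of their
#' eigenvalue. Only positive-eigenvalue axes carry coordinates; negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported unchanged, and the proportion explained is
#' taken over the positive part of the spectrum.
#'
#' @param d a [stats::dist] or symmetric matrix of dissimilarities.
#' @return object of class `sig_ordination`: list with `coordinates`
#'   (tibble `sample_id`, `Axis1`, ...), `eigenvalues`, `prop_explained`.
#' @export
pcoa <- function(d) {
  d <- as_distance(d)
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = matrix_to_tibble(coords),
      eigenvalues = eig,
      prop_explained = ifelse(pos, eig / sum(eig[pos]), 0)[pos]
    ),
    class = "sig_ordination"
  )
}

as_distance <- function(d) {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
    abort("Distance input must be symmetric.")
  }
  if (any(diag(m) != 0)) abort("Distance diagonal must be zero.")
  as.dist(m)
}

sig_test <- function(method, statistic, p_value, n_permutations = NA,
                     extras = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, extras = extras),
            class = "sig_test")
}

#' @export
print.sig_test <- function(x, ...) {
  cat("<sig_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4),
      if (!is.na(x$n_permutations)) {
        paste0(" (", x$n_permutations, " permutations)")
      } else "", "\n", sep = "")
  invisible(x)
}

# distance-based one-way sums of squares for given labels
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' Distance-based permutational MANOVA (PERMANOVA)
#'
#' One-way pseudo-F from distance-based sums of squares
#' (\eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}, within-group terms with
#' divisor \eqn{n_g}), with significance from free relabeling of samples:
#' \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1) / (n_{perm} + 1)}, so the
#' smallest attainable p at 999 permutations is 1/1000.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups cohort labels, one per sample (named vectors are aligned
#'   by the distance labels); at least 2 groups with 2+ samples each.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed making the permutation stream
#'   reproducible.
#' @return a `sig_test` with the pseudo-F statistic and permutation p.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_distance(d)
  ids <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  g <- resolve_groups(groups, ids)
  check_group_sizes(g)
  d2 <- as.matrix(d)^2
  f_obs <- permanova_f(d2, g)
  p <- local_seed(seed, permutation_p(function(perm) {
    permanova_f(d2, g[perm])
  }, f_obs, length(g), n_perm))
  sig_test("PERMANOVA", f_obs, p, n_perm,
           extras = list(group_n = as.list(table(g))))
}

check_group_sizes <- function(g) {
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (any(table(g) < 2)) {
    abort("Every group needs at least 2 samples.")
  }
}

permutation_p <- function(stat_fn, obs, n, n_perm) {
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (stat_fn(sample.int(n)) >= obs - 1e-12) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

anosim_r <- function(rk, groups, within) {
  rb <- mean(rk[!within])
  rw <- mean(rk[within])
  (rb - rw) / (length(rk) / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' \eqn{R = (\bar r_B - \bar r_W) / (M / 2)} with \eqn{M = n(n-1)/2}
#' ranked distances, +1 when all between-group distances exceed all
#' within-group ones and ~0 under exchangeable labels. Being rank-based, R
#' (and its permutation p) is invariant to monotone transformation of the
#' dissimilarities. Permutation p as in [permanova()].
#'
#' @inheritParams permanova
#' @return a `sig_test` with the R statistic and permutation p.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_distance(d)
  ids <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  g <- resolve_groups(groups, ids)
  check_group_sizes(g)
  rk <- rank(as.vector(d))
  n <- length(g)
  pair_i <- pair_j <- integer(0)
  # dist vector order: (2,1), (3,1), ..., (n,1), (3,2), ...
  for (col in seq_len(n - 1)) {
    pair_i <- c(pair_i, (col + 1):n)
    pair_j <- c(pair_j, rep(col, n - col))
  }
  within_for <- function(gg) gg[pair_i] == gg[pair_j]
  r_obs <- anosim_r(rk, g, within_for(g))
  p <- local_seed(seed, permutation_p(function(perm) {
    anosim_r(rk, g, within_for(g[perm]))
  }, r_obs, n, n_perm))
  sig_test("ANOSIM", r_obs, p, n_perm,
           extras = list(group_n = as.list(table(g))))
}

#' Hierarchical clustering vs cohort concordance
#'
#' Complete-linkage agglomeration of the dissimilarity matrix, cut at two
#' clusters; the 2x2 cluster-by-cohort table is tested with a two-sided
#' Fisher's exact test (table-probability method). With more than two
#' cohorts the dendrogram is still returned but the concordance test is
#' skipped with a warning.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups cohort labels, one per sample.
#' @return list with `dendrogram` (an [stats::hclust]), `clusters` (named
#'   integer vector) and `test` (a `sig_test`, or `NULL` if skipped).
#' @export
cluster_concordance <- function(d, groups) {
  d <- as_distance(d)
  ids <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  g <- resolve_groups(groups, ids)
  hc <- hclust(d, method = "complete")
  cl <- cutree(hc, k = 2)
  test <- NULL
  if (nlevels(g) == 2) {
    tab <- table(cluster = cl, cohort = g)
    ft <- fisher.test(tab, alternative = "two.sided")
    test <- sig_test("Fisher exact (cluster x cohort)",
                     unname(ft$estimate %||% NA_real_), ft$p.value,
                     extras = list(table = unclass(tab)))
  } else {
    warn("Concordance test skipped: needs exactly 2 cohorts.")
  }
  list(dendrogram = hc, clusters = cl, test = test)
}
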