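#' Leave-one-out averaged Pearson correlation p-value
#'
#' The edge statistic of the co-occurrence network: the Pearson
#' correlation is computed on the full sample, while its p-value is
#' averaged over subjects — for each left-out subject the two-sided
#' Pearson p is computed on the remaining \eqn{n - 1} samples (t statistic
#' with \eqn{n - 3} degrees of freedom) and the \eqn{n} p-values are
#' averaged arithmetically. Averaging over deletions damps p-values driven
#' by a single influential subject.
#'
#' @param x samples-by-features data frame or matrix with at least 5
#'   samples.
#' @param i,j feature names or column indices.
#' @return tibble with `r` (full-sample Pearson) and `p_avg`.
#' @export
loo_averaged_correlation <- function(x, i, j) {
  m <- as_feature_matrix(x)
  if (nrow(m) < 5) abort("Need at least 5 samples.")
  sub <- m[, c(i, j), drop = FALSE]
  res <- loo_p_matrix(sub)
  tibble::tibble(r = res$r[1, 2], p_avg = res$p[1, 2])
}

# All-pairs full-sample r and LOO-averaged p. Jackknife replicates with a
# zero-variance column get p = 1 for that replicate's pairs (warning).
loo_p_matrix <- function(m) {
  n <- nrow(m)
  r_full <- suppressWarnings(cor(m))
  p_sum <- matrix(0, ncol(m), ncol(m))
  warned <- FALSE
  for (k in seq_len(n)) {
    mk <- m[-k, , drop = FALSE]
    sds <- apply(mk, 2, function(v) max(v) - min(v))
    ck <- suppressWarnings(cor(mk))
    pk <- pearson_p(ck, df = n - 3)
    if (any(sds == 0)) {
      pk[sds == 0, ] <- 1
      pk[, sds == 0] <- 1
      warned <- TRUE
    }
    p_sum <- p_sum + pk
  }
  if (warned) warn("Zero-variance jackknife replicate(s): p set to 1.")
  list(r = r_full, p = p_sum / n)
}

#' Two-stage Benjamini-Hochberg FDR procedure
#'
#' The adaptive two-stage linear step-up procedure: a first BH pass at
#' level \eqn{q' = q/(1+q)} estimates the number of true nulls as
#' \eqn{m_0 = m - r_1} (with \eqn{r_1} first-stage rejections); if
#' \eqn{m_0 = 0} everything is rejected, otherwise a second BH pass runs
#' at level \eqn{q' m / m_0}. The adjusted q-values are the second-stage
#' BH-adjusted p-values rescaled by \eqn{m_0/m} (floored at p so q >= p),
#' and `rejected` is the two-stage decision at level `q_level`.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param q_level target FDR level (default 0.10).
#' @return tibble with columns `p`, `q`, `rejected` in input order; empty
#'   input gives an empty tibble.
#' @examples
#' two_stage_bh(c(0.001, 0.2, 0.9), q_level = 0.10)  # one rejection
#' @export
two_stage_bh <- function(p, q_level = 0.10) {
  stopifnot(q_level > 0, q_level < 1)
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(), q = numeric(),
                          rejected = logical()))
  }
  if (any(p <= 0 | p > 1 | is.na(p))) abort("p-values must lie in (0, 1].")
  m <- length(p)
  q_prime <- q_level / (1 + q_level)
  bh_adj <- p.adjust(p, method = "BH")
  r1 <- sum(bh_adj <= q_prime)
  m0 <- m - r1
  if (m0 == 0) {
    return(tibble::tibble(p = p, q = pmax(p, bh_adj * 0), rejected = TRUE))
  }
  q_adj <- pmax(p, bh_adj * m0 / m)
  rejected <- bh_adj <= q_prime * m / m0
  tibble::tibble(p = p, q = q_adj, rejected = rejected)
}

#' Build the pruned species co-occurrence network
#'
#' All pairwise full-sample Pearson correlations on normalized,
#' standardized abundances with leave-one-out averaged p-values
#' ([loo_averaged_correlation()]), pruned by the two-stage
#' Benjamini-Hochberg procedure at `fdr_level`. Surviving edges get their
#' correlation sign and a 1-8 thickness category from equal-count
#' quantile bins of q (8 = smallest q, i.e. thickest). Node cohort
#' affinity is the cohort with the higher mean normalized abundance.
#'
#' @param x prevalence-filtered, normalized samples-by-species table (data
#'   frame with `sample_id`, e.g. from [gaussianize()]), at least 5
#'   species.
#' @param groups two-level cohort labels, one per sample.
#' @param fdr_level two-stage BH level for edge pruning (default 0.10).
#' @param node_prevalence optional named vector of per-species prevalence
#'   (from [prevalence()] on the unfiltered counts) stored on the nodes.
#' @return object of class `sig_network`: tibbles `nodes` (species,
#'   affinity, prevalence, degree, betweenness, keystonness, sig) and
#'   `edges` (from, to, r, p, q, sign, thickness), plus `partition`
#'   (`NULL` until [consensus_sigs()] runs).
#' @export
build_network <- function(x, groups, fdr_level = 0.10,
                          node_prevalence = NULL) {
  m <- as_feature_matrix(x)
  if (ncol(m) < 5) abort("Need at least 5 species to build a network.")
  if (nrow(m) < 5) abort("Need at least 5 samples.")
  g <- factor(as.character(groups))
  if (nlevels(g) != 2) abort("Two cohorts required for node affinity.")

  species <- colnames(m)
  res <- loo_p_matrix(m)
  iu <- which(upper.tri(res$p), arr.ind = TRUE)
  edges_all <- tibble::tibble(
    from = species[iu[, 1]],
    to = species[iu[, 2]],
    r = res$r[iu],
    p = pmin(pmax(res$p[iu], .Machine$double.xmin), 1)
  )
  adj <- two_stage_bh(edges_all$p, q_level = fdr_level)
  edges <- edges_all |>
    dplyr::mutate(q = adj$q, rejected = adj$rejected) |>
    dplyr::filter(.data$rejected) |>
    dplyr::select(-"rejected") |>
    dplyr::mutate(sign = ifelse(.data$r >= 0, "positive", "negative"),
                  thickness = thickness_category(.data$q))
  if (nrow(edges) == 0) warn("No edge survived FDR pruning.")

  mean_by_cohort <- vapply(levels(g), function(lv) {
    colMeans(m[g == lv, , drop = FALSE])
  }, numeric(ncol(m)))
  affinity <- levels(g)[max.col(matrix(mean_by_cohort, ncol = 2),
                                ties.method = "first")]
  nodes <- tibble::tibble(
    species = species,
    affinity = affinity,
    prevalence = if (!is.null(node_prevalence)) {
      unname(node_prevalence[species])
    } else NA_real_,
    degree = NA_integer_, betweenness = NA_real_, keystonness = NA_real_,
    sig = NA_integer_
  )
  net <- structure(list(nodes = nodes, edges = edges, partition = NULL),
                   class = "sig_network")
  node_centralities(net)
}

# Equal-count 8-quantile bins of q; smallest q -> category 8 (thickest).
thickness_category <- function(q, n_cat = 8L) {
  if (length(q) == 0) return(integer(0))
  if (length(unique(q)) == 1) return(rep(n_cat, length(q)))
  br <- unique(quantile(q, probs = seq(0, 1, length.out = n_cat + 1)))
  bin <- cut(q, breaks = br, include.lowest = TRUE, labels = FALSE)
  as.integer(max(bin) - bin + (n_cat - max(bin) + 1L))
}

#' @export
print.sig_network <- function(x, ...) {
  cat("<sig_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (!is.null(x$partition)) {
        paste0(", ", length(unique(x$partition$membership$sig)), " SIGs")
      } else "", "\n", sep = "")
  invisible(x)
}

#' Node centralities of the pruned network
#'
#' Degree is the incident-edge count; betweenness is shortest-path
#' betweenness on the unweighted pruned graph, normalized by
#' \eqn{(n-1)(n-2)/2}; keystonness — the display quantity scaling node
#' labels in the network figure — is the normalized betweenness.
#'
#' @param net a `sig_network`.
#' @return the network with `degree`, `betweenness` and `keystonness`
#'   filled in on `$nodes`.
#' @export
node_centralities <- function(net) {
  stopifnot(inherits(net, "sig_network"))
  g <- network_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  ord <- match(net$nodes$species, igraph::V(g)$name)
  net$nodes$degree <- as.integer(deg[ord])
  net$nodes$betweenness <- unname(btw[ord])
  net$nodes$keystonness <- unname(btw[ord])
  net
}

#' Consensus Louvain detection of species-interacting groups (SIGs)
#'
#' Louvain modularity optimization runs `iterations` times at the given
#' resolution, each run under a random node processing order. Community
#' attraction uses the positive edges only, weighted by r: in a signed
#' correlation network a negative edge is evidence that two species
#' belong to *opposing* groups, so letting its magnitude pull them into
#' one community would merge exactly the SIGs the analysis is meant to
#' separate; negative edges stay in the network and drive the opposition
#' test instead. The co-classification matrix \eqn{C_{ij}} — the
#' fraction of runs placing species i and j in one community — defines
#' the consensus: SIGs are the connected components of the graph with
#' edges \eqn{C_{ij} > 0.5}; per-species stability is the mean \eqn{C}
#' over the species' SIG partners (1 for singletons). Per-SIG cohort
#' composition is the percentage of member species whose affinity points
#' to each cohort. Disconnected species form singleton SIGs.
#'
#' @param net a `sig_network` with at least one edge (edgeless networks
#'   yield all-singleton SIGs).
#' @param iterations number of Louvain runs (default 100).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed; the same seed reproduces the partition.
#' @return the network with `$partition` set: `membership` (tibble
#'   species, sig, stability), `composition` (tibble sig, n_species, one
#'   percentage column per cohort affinity), and the consensus matrix.
#' @export
consensus_sigs <- function(net, iterations = 100, resolution = 1.0,
                           seed = NULL) {
  stopifnot(inherits(net, "sig_network"))
  species <- net$nodes$species
  ns <- length(species)
  pos_edges <- net$edges[net$edges$r > 0, , drop = FALSE]
  if (nrow(pos_edges) == 0) {
    memb <- tibble::tibble(species = species, sig = seq_len(ns),
                           stability = 1)
    net$partition <- list(membership = memb,
                          composition = sig_composition(memb, net$nodes),
                          consensus = diag(ns))
    net$nodes$sig <- memb$sig
    return(net)
  }
  g <- igraph::graph_from_data_frame(
    pos_edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = species))
  igraph::E(g)$weight <- pos_edges$r

  local_seed(seed, {
    C <- matrix(0, ns, ns)
    for (it in seq_len(iterations)) {
      perm <- sample.int(ns)
      gp <- igraph::permute(g, perm)  # randomized node processing order
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                    resolution = resolution)
      memb <- igraph::membership(cl)[species]  # back to original order
      C <- C + outer(memb, memb, "==")
    }
    C <- C / iterations
    cons_adj <- C > 0.5
    diag(cons_adj) <- FALSE
    gc <- igraph::graph_from_adjacency_matrix(cons_adj, mode = "undirected")
    comp <- igraph::components(gc)$membership
    # relabel SIGs by decreasing size, then first appearance
    sizes <- table(comp)
    ord <- order(-as.vector(sizes), as.integer(names(sizes)))
    relabel <- setNames(seq_along(ord), names(sizes)[ord])
    sig_id <- as.integer(relabel[as.character(comp)])
    stability <- vapply(seq_len(ns), function(i) {
      partners <- setdiff(which(sig_id == sig_id[i]), i)
      if (length(partners) == 0) 1 else mean(C[i, partners])
    }, numeric(1))
    memb_tbl <- tibble::tibble(species = species, sig = sig_id,
                               stability = stability)
    net$partition <- list(membership = memb_tbl,
                          composition = sig_composition(memb_tbl, net$nodes),
                          consensus = C)
    net$nodes$sig <- sig_id
    net
  })
}

sig_composition <- function(membership, nodes) {
  df <- dplyr::left_join(membership, nodes[, c("species", "affinity")],
                         by = "species")
  df |>
    dplyr::count(.data$sig, .data$affinity) |>
    dplyr::group_by(.data$sig) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "affinity",
                       values_from = c("n", "pct"), values_fill = 0)
}

#' Fisher test of cohort opposition between two SIGs
#'
#' Builds the 2x2 table of SIG membership (a vs b) by node cohort affinity
#' and tests it with a two-sided Fisher's exact test; a small p says the
#' two SIGs are inhabited by species of opposite cohorts. Nodes without an
#' affinity label are excluded with a warning.
#'
#' @param net a `sig_network` with a computed partition.
#' @param sig_a,sig_b SIG identifiers.
#' @return a `sig_test` with the odds ratio and exact p, the table in
#'   `$extras`.
#' @export
sig_cohort_fisher <- function(net, sig_a, sig_b) {
  stopifnot(inherits(net, "sig_network"))
  if (is.null(net$partition)) abort("Run consensus_sigs() first.")
  df <- dplyr::left_join(net$partition$membership,
                         net$nodes[, c("species", "affinity")],
                         by = "species") |>
    dplyr::filter(.data$sig %in% c(sig_a, sig_b))
  if (!all(c(sig_a, sig_b) %in% df$sig)) abort("Both SIGs must be nonempty.")
  if (anyNA(df$affinity)) {
    warn("Nodes without affinity excluded from the opposition test.")
    df <- df[!is.na(df$affinity), ]
  }
  tab <- table(sig = factor(df$sig, levels = c(sig_a, sig_b)),
               affinity = factor(df$affinity,
                                 levels = sort(unique(net$nodes$affinity))))
  if (ncol(tab) < 2) {
    tab <- cbind(tab, `(other)` = c(0L, 0L))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  sig_test("Fisher exact (SIG x affinity)",
           unname(ft$estimate %||% NA_real_), ft$p.value,
           extras = list(table = unclass(tab)))
}
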