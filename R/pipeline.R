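#' Run the full microbiome network pipeline on a cohort study
#'
#' Convenience wrapper chaining the stages in study order: relative
#' abundances, alpha diversity with per-index Mann-Whitney tests,
#' Bray-Curtis beta diversity with PCoA, PERMANOVA and ANOSIM, cluster-
#' cohort concordance, prevalence filtering and gaussianization, the
#' pruned co-occurrence network with consensus SIGs and centralities, and
#' (when the study carries metabolites) the volcano table and the
#' cohort-restricted species-metabolite cross-correlation.
#'
#' @param study a [cohort_study()].
#' @param config a [run_config()]; its seed drives every randomized stage.
#' @param crosscor_cohort cohort for the cross-correlation stage (default:
#'   second cohort level).
#' @return named list with elements `alpha`, `alpha_tests`, `distance`,
#'   `ordination`, `permanova`, `anosim`, `concordance`, `network`,
#'   `sig_tests` (pairwise SIG opposition, when 2+ SIGs), `volcano`,
#'   `crosscor` (the last two `NULL` without metabolites).
#' @export
run_sig_pipeline <- function(study, config = run_config(),
                             crosscor_cohort = NULL) {
  stopifnot(inherits(study, "cohort_study"), inherits(config, "run_config"))
  g <- cohort_labels(study)
  rel <- to_relative_abundance(study$abundance)

  alpha <- alpha_diversity(rel)
  alpha_tests <- list(
    richness = group_difference_test(alpha$richness, g),
    shannon = group_difference_test(alpha$shannon, g)
  )

  d <- bray_curtis(rel)
  ord <- pcoa(d)
  perm <- permanova(d, g, n_perm = config$n_permutations,
                    seed = config$seed)
  ano <- anosim(d, g, n_perm = config$n_permutations,
                seed = config$seed + 1L)
  conc <- cluster_concordance(d, g)

  prev <- prevalence(study$abundance)
  filt <- prevalence_filter(rel, config$prevalence_min)
  norm <- gaussianize(filt)
  net <- build_network(norm, g, fdr_level = config$fdr_level,
                       node_prevalence = prev)
  net <- consensus_sigs(net, iterations = config$louvain_iterations,
                        resolution = config$louvain_resolution,
                        seed = config$seed + 2L)

  sig_tests <- NULL
  sig_sizes <- table(net$partition$membership$sig)
  big <- as.integer(names(sig_sizes)[sig_sizes >= 2])
  if (length(big) >= 2) {
    pairs <- utils::combn(big[seq_len(min(length(big), 4))], 2)
    sig_tests <- lapply(seq_len(ncol(pairs)), function(k) {
      sig_cohort_fisher(net, pairs[1, k], pairs[2, k])
    })
    names(sig_tests) <- apply(pairs, 2, paste, collapse = "-")
  }

  volcano <- crosscor <- NULL
  if (!is.null(study$metabolites)) {
    volcano <- volcano_table(study$metabolites, g)
    coh <- crosscor_cohort %||% sort(unique(g))[2]
    if (sum(g == coh) >= 5) {
      crosscor <- cross_correlation(norm, study$metabolites, groups = g,
                                    cohort = coh,
                                    fdr_level = config$fdr_level)
    }
  }

  list(alpha = alpha, alpha_tests = alpha_tests, distance = d,
       ordination = ord, permanova = perm, anosim = ano,
       concordance = conc, network = net, sig_tests = sig_tests,
       volcano = volcano, crosscor = crosscor)
}
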