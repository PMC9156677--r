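#' Parameters of the synthetic cohort-study generator
#'
#' The defaults reproduce the dimensions and planted effects of the
#' two-cohort housing study the pipeline was built around: 10 mice per
#' cohort, 145 bacterial species sequenced to a mean depth of 28123 reads,
#' 37 quantified fecal metabolites, two 7-species correlated blocks
#' (candidate species-interacting groups) at within-block latent
#' correlation 0.8, a one-log-unit cohort shift on the block species, and
#' metabolite fold changes of 2.81 for formate and 1.35 for acetate
#' (enriched cohort over reference).
#'
#' @param n_per_cohort samples per cohort.
#' @param n_species number of species columns.
#' @param n_metabolites number of metabolite columns.
#' @param n_blocks number of planted correlated species blocks.
#' @param block_size species per block.
#' @param block_correlation within-block latent Pearson correlation,
#'   in `(-1, 1)`.
#' @param cohort_shift latent (log-scale) mean shift added to each block
#'   species in its enriched cohort.
#' @param metabolite_folds named numeric vector of planted enriched/reference
#'   mean concentration ratios; names become metabolite names.
#' @param metabolite_cv coefficient of variation of the log-normal
#'   metabolite noise.
#' @param zero_inflation probability of zeroing a count of a
#'   non-differential, low-baseline species.
#' @param depth_mean mean Poisson sequencing depth per sample.
#' @param cohorts length-2 character vector `(reference, enriched)`.
#' @return a list of class `simulation_params`.
#' @export
simulation_params <- function(n_per_cohort = 10L, n_species = 145L,
                              n_metabolites = 37L, n_blocks = 2L,
                              block_size = 7L, block_correlation = 0.8,
                              cohort_shift = 1.0,
                              metabolite_folds = c(formate = 2.81,
                                                   acetate = 1.35),
                              metabolite_cv = 0.2, zero_inflation = 0.3,
                              depth_mean = 28123, cohorts = c("SE", "EE")) {
  if (n_blocks * block_size > n_species) {
    abort("Planted blocks exceed the species count (block overlap/overflow).")
  }
  if (abs(block_correlation) >= 1) {
    abort("`block_correlation` must lie in (-1, 1).")
  }
  stopifnot(n_per_cohort >= 2, n_metabolites >= length(metabolite_folds),
            zero_inflation >= 0, zero_inflation <= 1, depth_mean > 0,
            length(cohorts) == 2, metabolite_cv >= 0)
  if (any(metabolite_folds <= 0)) abort("Fold ratios must be positive.")
  structure(
    list(n_per_cohort = as.integer(n_per_cohort),
         n_species = as.integer(n_species),
         n_metabolites = as.integer(n_metabolites),
         n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
         block_correlation = block_correlation, cohort_shift = cohort_shift,
         metabolite_folds = metabolite_folds, metabolite_cv = metabolite_cv,
         zero_inflation = zero_inflation, depth_mean = depth_mean,
         cohorts = cohorts),
    class = "simulation_params"
  )
}

#' Simulate a cohort study with planted structure
#'
#' Abundances follow a logistic-normal/multinomial model: each sample draws
#' a latent Gaussian vector with per-species baselines, a shared factor per
#' planted block inducing within-block correlation, and a cohort mean shift
#' on the block species in their enriched cohort (odd blocks are enriched in
#' the second cohort, even blocks in the first, so consecutive blocks
#' oppose each other). The latent vector passes through a softmax to a
#' composition, counts are multinomial at a Poisson-distributed depth, and
#' zero-inflation is then applied to non-differential species with
#' below-median baselines. Metabolite concentrations are log-normal with
#' the planted fold ratios on the enriched cohort's mean.
#'
#' The same `seed` yields bit-identical output.
#'
#' @param params a [simulation_params()].
#' @param seed integer seed.
#' @return list with elements `study` (a [cohort_study()] of counts) and
#'   `truth` (a `ground_truth` list: `sig_membership`,
#'   `differential_species`, `differential_metabolites`, `seed`).
#' @export
simulate_cohort_study <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  local_seed(seed, {
    p <- params
    n <- 2L * p$n_per_cohort
    cohort <- rep(p$cohorts, each = p$n_per_cohort)
    sample_id <- sprintf("m%02d", seq_len(n))
    species <- sprintf("sp%03d", seq_len(p$n_species))

    # planted block membership: block b = species (b-1)*bs+1 .. b*bs
    block_of <- rep(NA_integer_, p$n_species)
    if (p$n_blocks > 0 && p$block_size > 0) {
      for (b in seq_len(p$n_blocks)) {
        block_of[((b - 1L) * p$block_size + 1L):(b * p$block_size)] <- b
      }
    }
    # odd blocks enriched in cohorts[2], even blocks in cohorts[1]
    enriched_cohort <- ifelse(is.na(block_of), NA_character_,
                              ifelse(block_of %% 2L == 1L,
                                     p$cohorts[2], p$cohorts[1]))

    baseline <- rnorm(p$n_species, mean = 0, sd = 1.0)
    rho <- p$block_correlation
    z <- matrix(rnorm(n * p$n_species), n, p$n_species)
    if (!is.na(rho) && rho != 0 && p$n_blocks > 0) {
      f <- matrix(rnorm(n * p$n_blocks), n, p$n_blocks)
      for (j in which(!is.na(block_of))) {
        z[, j] <- sqrt(abs(rho)) * sign(rho) * f[, block_of[j]] +
          sqrt(1 - abs(rho)) * z[, j]
      }
    }
    z <- sweep(z, 2, baseline, "+")
    if (p$cohort_shift != 0) {
      for (j in which(!is.na(block_of))) {
        z[cohort == enriched_cohort[j], j] <-
          z[cohort == enriched_cohort[j], j] + p$cohort_shift
      }
    }

    comp <- softmax_rows(z)
    depth <- rpois(n, p$depth_mean)
    counts <- t(vapply(seq_len(n),
                       function(i) as.numeric(rmultinom(1, depth[i], comp[i, ])),
                       numeric(p$n_species)))

    differential <- !is.na(block_of) & p$cohort_shift != 0
    # planted-block species keep their correlation structure intact
    zi_eligible <- is.na(block_of) & baseline < stats::median(baseline)
    if (p$zero_inflation > 0 && any(zi_eligible)) {
      mask <- matrix(rbinom(n * sum(zi_eligible), 1,
                            1 - p$zero_inflation),
                     n, sum(zi_eligible))
      counts[, zi_eligible] <- counts[, zi_eligible] * mask
    }
    dimnames(counts) <- list(sample_id, species)

    # metabolites: log-normal around per-metabolite baselines
    met_names <- names(p$metabolite_folds)
    extra <- p$n_metabolites - length(met_names)
    if (extra > 0) met_names <- c(met_names, sprintf("met%02d", seq_len(extra)))
    folds <- setNames(rep(1, p$n_metabolites), met_names)
    folds[names(p$metabolite_folds)] <- p$metabolite_folds
    sdlog <- sqrt(log(1 + p$metabolite_cv^2))
    base_meanlog <- rnorm(p$n_metabolites, mean = log(20), sd = 1)
    meanlog <- outer(rep(0, n), base_meanlog, "+")
    meanlog[cohort == p$cohorts[2], ] <-
      sweep(meanlog[cohort == p$cohorts[2], , drop = FALSE], 2,
            log(folds), "+")
    metab <- exp(meanlog + matrix(rnorm(n * p$n_metabolites, sd = sdlog),
                                  n, p$n_metabolites))
    dimnames(metab) <- list(sample_id, met_names)

    study <- cohort_study(
      matrix_to_tibble(counts),
      tibble::tibble(sample_id = sample_id, cohort = cohort),
      matrix_to_tibble(metab)
    )
    diff_fold <- p$metabolite_folds[p$metabolite_folds != 1]
    truth <- structure(
      list(
        sig_membership = tibble::tibble(
          species = species[!is.na(block_of)],
          block = block_of[!is.na(block_of)]),
        differential_species = if (p$cohort_shift != 0) {
          tibble::tibble(species = species[differential],
                         enriched_cohort = enriched_cohort[differential],
                         log_fold = p$cohort_shift)
        } else {
          tibble::tibble(species = character(),
                         enriched_cohort = character(), log_fold = numeric())
        },
        differential_metabolites = tibble::tibble(
          metabolite = names(diff_fold),
          fold = unname(diff_fold)),
        seed = as.integer(seed)
      ),
      class = "ground_truth"
    )
    list(study = study, truth = truth)
  })
}

#' Simulate a null cohort study
#'
#' The same generator with every cohort effect, block correlation and
#' metabolite fold removed: cohort labels are exchangeable, so the output
#' is the reference distribution for type-I-error and false-discovery-rate
#' calibration.
#'
#' @inheritParams simulate_cohort_study
#' @return as [simulate_cohort_study()]; `truth` has empty differential
#'   maps and no planted blocks.
#' @export
simulate_null_study <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  null_params <- params
  null_params$block_correlation <- 0
  null_params$cohort_shift <- 0
  null_params$metabolite_folds <-
    setNames(rep(1, length(params$metabolite_folds)),
             names(params$metabolite_folds))
  out <- simulate_cohort_study(null_params, seed)
  out$truth$sig_membership <- out$truth$sig_membership[0, ]
  out
}
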