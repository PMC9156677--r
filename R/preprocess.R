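#' Convert counts to relative abundances
#'
#' Divides every sample row by its total so rows sum to one; within-row
#' ratios are preserved. Idempotent on tables that are already relative.
#'
#' @param abundance data frame with `sample_id` plus numeric species
#'   columns, or a numeric matrix.
#' @return tibble of the same shape with rows summing to 1, carrying the
#'   attribute `transform = "relative"`.
#' @examples
#' to_relative_abundance(tibble::tibble(sample_id = "a", x = 2, y = 2, z = 4))
#' @export
to_relative_abundance <- function(abundance) {
  m <- as_feature_matrix(abundance)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(paste0("All-zero sample row(s): ",
                 toString(head(rownames(m)[rs <= 0], 5))))
  }
  out <- matrix_to_tibble(m / rs)
  attr(out, "transform") <- "relative"
  out
}

#' Filter species by prevalence
#'
#' Keeps features detected (value strictly positive) in at least
#' `min_prevalence` of the samples; the comparison is inclusive, so a
#' feature seen in exactly 5% of samples survives a 0.05 threshold. Column
#' order of the survivors is preserved.
#'
#' @param abundance data frame with `sample_id` plus numeric feature
#'   columns, or a matrix.
#' @param min_prevalence fraction of samples in `[0, 1]`.
#' @return tibble restricted to the surviving features.
#' @export
prevalence_filter <- function(abundance, min_prevalence = 0.05) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  m <- as_feature_matrix(abundance)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) {
    abort("Prevalence filter removed every feature.")
  }
  out <- matrix_to_tibble(m[, keep, drop = FALSE])
  attr(out, "prevalence") <- prev[keep]
  out
}

#' Per-feature prevalence
#'
#' @param abundance data frame or matrix of samples by features.
#' @return named numeric vector: fraction of samples with a strictly
#'   positive value, per feature.
#' @export
prevalence <- function(abundance) {
  colMeans(as_feature_matrix(abundance) > 0)
}

#' Rank-based gaussianization with standardization
#'
#' Maps each feature through its ranks to standard-normal quantiles at
#' plotting positions `(rank - 0.5) / n` (ties share their average rank),
#' then centers and scales to mean 0 and population variance 1. The result
#' is strictly Gaussian-shaped per feature and monotone in the input, which
#' puts features with very different dynamic ranges — relative abundances,
#' concentrations — on one common scale before multivariate and network
#' analysis.
#'
#' Constant features cannot be ranked meaningfully and are passed through
#' as all-zero columns with a warning.
#'
#' @param x data frame with `sample_id` plus numeric feature columns, or a
#'   matrix, with at least 3 samples.
#' @return tibble of transformed values with attribute
#'   `transform = "quantile-normal-standardized"`.
#' @export
gaussianize <- function(x) {
  m <- as_feature_matrix(x)
  n <- nrow(m)
  if (n < 3) abort("gaussianize needs at least 3 samples.")
  out <- apply(m, 2, function(v) {
    if (max(v) == min(v)) return(rep(NA_real_, n))
    q <- qnorm((rank(v, ties.method = "average") - 0.5) / n)
    q <- q - mean(q)
    q / sqrt(mean(q^2))  # population variance 1
  })
  const <- colSums(is.na(out)) == n
  if (any(const)) {
    warn(paste0("Constant feature(s) passed through as zeros: ",
                toString(head(colnames(m)[const], 5))))
    out[, const] <- 0
  }
  res <- matrix_to_tibble(out)
  attr(res, "transform") <- "quantile-normal-standardized"
  res
}
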