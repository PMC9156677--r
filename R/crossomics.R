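#' Species-metabolite cross-correlation
#'
#' Pearson correlation of every species against every metabolite within a
#' chosen cohort (or across all samples): per cell the full-sample r and
#' its two-sided p (t statistic, \eqn{n - 2} df), the Fisher
#' variance-stabilized z-score \eqn{z = \mathrm{atanh}(r)\sqrt{n - 3}},
#' and a two-stage Benjamini-Hochberg q computed across all cells. The
#' leave-one-out averaged p of the network module is reported alongside
#' the plain p for every cell. Cells where either variable is constant in
#' the cohort are marked undefined (NA).
#'
#' @param species data frame with `sample_id` plus species columns (use
#'   normalized values for comparability), or a matrix.
#' @param metabolites data frame with `sample_id` plus metabolite columns,
#'   or a matrix; same samples, same order.
#' @param groups optional cohort labels (needed when `cohort` is given).
#' @param cohort optional cohort label restricting the analysis (at least
#'   5 samples must remain).
#' @param fdr_level two-stage BH level for flagging cells (default 0.10).
#' @return object of class `sig_crosscor`: matrices `r`, `p`, `p_loo`,
#'   `z`, `q`, logical `flagged`, the sample size `n` and a tibble
#'   `associations` of all defined cells sorted by p.
#' @export
cross_correlation <- function(species, metabolites, groups = NULL,
                              cohort = NULL, fdr_level = 0.10) {
  ms <- as_feature_matrix(species)
  mm <- as_feature_matrix(metabolites)
  if (nrow(ms) != nrow(mm)) abort("Tables must share the sample set.")
  if (!is.null(rownames(ms)) && !is.null(rownames(mm)) &&
      !identical(rownames(ms), rownames(mm))) {
    abort("Tables must share the sample order.")
  }
  if (!is.null(cohort)) {
    if (is.null(groups)) abort("`groups` needed to filter by cohort.")
    keep <- as.character(groups) == cohort
    ms <- ms[keep, , drop = FALSE]
    mm <- mm[keep, , drop = FALSE]
  }
  n <- nrow(ms)
  if (n < 5) abort("Need at least 5 samples in the (filtered) cohort.")

  const_s <- apply(ms, 2, function(v) max(v) == min(v))
  const_m <- apply(mm, 2, function(v) max(v) == min(v))
  r <- suppressWarnings(cor(ms, mm))
  r[const_s, ] <- NA
  r[, const_m] <- NA
  p <- pearson_p(r, df = n - 2)
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)

  # LOO-averaged p on the joined table, subset to the cross block
  joint <- cbind(ms, mm)
  loo <- loo_p_matrix(joint)
  p_loo <- loo$p[seq_len(ncol(ms)), ncol(ms) + seq_len(ncol(mm)),
                 drop = FALSE]
  p_loo[is.na(r)] <- NA

  ok <- !is.na(p)
  q <- flagged <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  if (any(ok)) {
    adj <- two_stage_bh(pmin(pmax(p[ok], .Machine$double.xmin), 1),
                        q_level = fdr_level)
    q[ok] <- adj$q
    flagged[ok] <- adj$rejected
  }
  flagged <- flagged == 1

  assoc <- tibble::as_tibble(expand.grid(
    species = rownames(r) %||% colnames(ms),
    metabolite = colnames(r) %||% colnames(mm),
    stringsAsFactors = FALSE))
  assoc$species <- rep(colnames(ms), times = ncol(mm))
  assoc$metabolite <- rep(colnames(mm), each = ncol(ms))
  assoc$r <- as.vector(r)
  assoc$p <- as.vector(p)
  assoc$p_loo <- as.vector(p_loo)
  assoc$z <- as.vector(z)
  assoc$q <- as.vector(q)
  assoc$flagged <- as.vector(flagged)
  assoc <- assoc[!is.na(assoc$r), ]
  assoc <- assoc[order(assoc$p), ]

  structure(list(r = r, p = p, p_loo = p_loo, z = z, q = q,
                 flagged = flagged, n = n,
                 associations = tibble::as_tibble(assoc)),
            class = "sig_crosscor")
}

#' @export
print.sig_crosscor <- function(x, ...) {
  cat("<sig_crosscor> ", nrow(x$r), " species x ", ncol(x$r),
      " metabolites, n = ", x$n, "; ",
      sum(x$flagged, na.rm = TRUE), " cell(s) flagged\n", sep = "")
  invisible(x)
}

#' Clustered z-score matrix for a cross-correlation heatmap
#'
#' Fisher z-scores with species rows reordered by complete-linkage
#' clustering of their correlation profiles (Euclidean distance on the
#' rows of z), so species with similar metabolite associations sit in
#' adjacent rows.
#'
#' @param res a [cross_correlation()] result.
#' @return tibble: `species` plus one z-score column per metabolite, in
#'   dendrogram order.
#' @export
heatmap_matrix <- function(res) {
  stopifnot(inherits(res, "sig_crosscor"))
  z <- res$z
  z[!is.finite(z)] <- 0
  ord <- seq_len(nrow(z))
  if (nrow(z) > 2) {
    hc <- hclust(dist(z), method = "complete")
    ord <- hc$order
  }
  out <- tibble::as_tibble(z[ord, , drop = FALSE], rownames = "species")
  out
}
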