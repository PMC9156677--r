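# broom-style tidiers for the pipeline's result objects.

#' Tidy a permutation/exact test result
#'
#' @param x a `sig_test`.
#' @param ... unused.
#' @return one-row tibble: `method`, `statistic`, `p_value`,
#'   `n_permutations`.
#' @method tidy sig_test
#' @export
tidy.sig_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n_permutations = x$n_permutations)
}

#' Tidy a PLS-DA model into per-feature VIP scores
#'
#' @param x a `sig_plsda`.
#' @param ... unused.
#' @return tibble `feature`, `vip`, sorted by decreasing VIP.
#' @method tidy sig_plsda
#' @export
tidy.sig_plsda <- function(x, ...) {
  tibble::tibble(feature = names(x$vip), vip = unname(x$vip)) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' One-row summary of a PLS-DA model
#'
#' @param x a `sig_plsda`.
#' @param ... unused.
#' @return tibble with component count, feature count, class labels and
#'   training accuracy under the nearest-centroid rule.
#' @method glance sig_plsda
#' @export
glance.sig_plsda <- function(x, ...) {
  train_acc <- {
    scores <- x$T
    cent <- vapply(x$levels, function(lv) {
      colMeans(scores[x$y == lv, , drop = FALSE])
    }, numeric(ncol(scores)))
    cent <- matrix(cent, ncol = 2)
    d2 <- vapply(1:2, function(k) rowSums(sweep(scores, 2, cent[, k])^2),
                 numeric(nrow(scores)))
    mean(x$levels[max.col(-matrix(d2, ncol = 2))] == as.character(x$y))
  }
  tibble::tibble(n_components = x$n_components,
                 n_features = length(x$features),
                 classes = paste(x$levels, collapse = "/"),
                 train_accuracy = train_acc)
}

#' Tidy a double cross-validation report
#'
#' @param x a `sig_double_cv`.
#' @param ... unused.
#' @return tibble `class`, `mean_rate`, `sd_rate` (percent), `repeats`.
#' @method tidy sig_double_cv
#' @export
tidy.sig_double_cv <- function(x, ...) {
  dplyr::mutate(x$rates, repeats = x$repeats)
}

#' Tidy a network into its edge list
#'
#' @param x a `sig_network`.
#' @param ... unused.
#' @return tibble of pruned edges with r, p, q, sign and thickness.
#' @method tidy sig_network
#' @export
tidy.sig_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a network
#'
#' @param x a `sig_network`.
#' @param ... unused.
#' @return tibble with node, edge and SIG counts and the positive-edge
#'   fraction.
#' @method glance sig_network
#' @export
glance.sig_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_sigs = if (!is.null(x$partition)) {
      length(unique(x$partition$membership$sig))
    } else NA_integer_,
    prop_positive = if (nrow(x$edges) > 0) {
      mean(x$edges$sign == "positive")
    } else NA_real_
  )
}

#' Tidy an ordination into sample coordinates
#'
#' @param x a `sig_ordination`.
#' @param ... unused.
#' @return tibble of sample coordinates on the positive axes.
#' @method tidy sig_ordination
#' @export
tidy.sig_ordination <- function(x, ...) {
  x$coordinates
}

#' Tidy a cross-correlation result into the cell list
#'
#' @param x a `sig_crosscor`.
#' @param ... unused.
#' @return tibble of species-metabolite cells sorted by p.
#' @method tidy sig_crosscor
#' @export
tidy.sig_crosscor <- function(x, ...) {
  x$associations
}
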