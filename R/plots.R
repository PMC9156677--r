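# ggplot2 graphics for the pipeline's result objects.

#' Ordination scatter plot
#'
#' First two principal coordinate axes, optionally colored by cohort, with
#' the proportion of (positive-eigenvalue) variance on the axis labels.
#'
#' @param object a `sig_ordination` from [pcoa()].
#' @param groups optional cohort labels named by (or ordered as) the
#'   samples.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sig_ordination
#' @export
autoplot.sig_ordination <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("Need at least two ordination axes to plot.")
  pe <- object$prop_explained
  if (!is.null(groups)) {
    df$cohort <- as.character(resolve_groups(groups, df$sample_id))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * pe[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * pe[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cohort), size = 2.5)
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
}

#' PLS-DA latent-variable score plot
#'
#' @param object a `sig_plsda`; needs at least 2 components.
#' @param ... unused.
#' @return a ggplot of LV1 vs LV2 scores colored by class.
#' @method autoplot sig_plsda
#' @export
autoplot.sig_plsda <- function(object, ...) {
  if (object$n_components < 2) abort("Score plot needs 2+ components.")
  df <- tibble::tibble(LV1 = object$T[, 1], LV2 = object$T[, 2],
                       class = as.character(object$y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$LV1, y = .data$LV2,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::stat_ellipse(level = 0.9, linetype = 2) +
    ggplot2::theme_minimal()
}

#' Volcano plot of two-cohort metabolite changes
#'
#' @param volcano tibble from [volcano_table()].
#' @param p_cut significance line (default 0.05).
#' @param fr_cut fold-ratio line on the log2 scale (default 1, i.e. 2x).
#' @return a ggplot.
#' @export
plot_volcano <- function(volcano, p_cut = 0.05, fr_cut = 1) {
  volcano <- dplyr::mutate(
    volcano,
    status = dplyr::case_when(
      .data$p_value <= p_cut & .data$log2_fr >= fr_cut ~ "up",
      .data$p_value <= p_cut & .data$log2_fr <= -fr_cut ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(volcano,
                  ggplot2::aes(x = .data$log2_fr, y = .data$neg_log10_p,
                               colour = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-fr_cut, fr_cut), linetype = 3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d1495b", down = "#30638e", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold ratio", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Alpha-diversity boxplots by cohort
#'
#' @param alpha tibble from [alpha_diversity()].
#' @param groups cohort labels named by (or ordered as) the samples.
#' @return a ggplot with one panel per index.
#' @export
plot_alpha_diversity <- function(alpha, groups) {
  alpha$cohort <- as.character(resolve_groups(groups, alpha$sample_id))
  long <- tidyr::pivot_longer(alpha, c("richness", "shannon"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$value,
                                     fill = .data$cohort)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1.2) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Species network plot with SIG coloring
#'
#' Fruchterman-Reingold layout of the pruned network; node color = SIG,
#' node size = keystonness, edge color = correlation sign, edge width =
#' thickness category.
#'
#' @param object a `sig_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sig_network
#' @export
autoplot.sig_network <- function(object, seed = 1, ...) {
  g <- network_igraph(object)
  xy <- local_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(nodes[, c("species", "x", "y")],
                     by = c(from = "species")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes[, c("species", "x", "y")],
                     by = c(to = "species"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$sign,
                   linewidth = .data$thickness), alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   size = .data$keystonness,
                   fill = factor(.data$sig)),
      shape = 21) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#d1495b", negative = "#30638e")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::labs(fill = "SIG") +
    ggplot2::theme_void()
}

#' Cross-correlation heatmap
#'
#' Tile map of Fisher z-scores with species rows in clustered order (see
#' [heatmap_matrix()]).
#'
#' @param res a [cross_correlation()] result.
#' @return a ggplot.
#' @export
plot_crosscor_heatmap <- function(res) {
  hm <- heatmap_matrix(res)
  long <- tidyr::pivot_longer(hm, -"species", names_to = "metabolite",
                              values_to = "z")
  long$species <- factor(long$species, levels = rev(hm$species))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metabolite,
                                     y = .data$species, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#30638e", mid = "white",
                                  high = "#d1495b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
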