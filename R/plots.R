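#' @import ggplot2
NULL

#' Alpha-diversity boxplots by group
#'
#' @param alpha tibble from [alpha_diversity()].
#' @param metadata tibble with `sample` and `group` (and optionally
#'   `timepoint`, used for faceting).
#' @param index which index to plot.
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(alpha, metadata,
                                 index = c("shannon", "simpson", "chao1",
                                           "evenness")) {
  index <- match.arg(index)
  d <- left_join(alpha, metadata, by = "sample")
  p <- ggplot(d, aes(x = .data$group, y = .data[[index]],
                     fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    geom_jitter(width = 0.15, size = 1) +
    labs(x = NULL, y = index) +
    theme_minimal() +
    theme(legend.position = "none")
  if ("timepoint" %in% names(d)) {
    p <- p + facet_wrap(~timepoint, labeller = label_both)
  }
  p
}

#' Ordination plot for a PCoA result
#'
#' @param object an `mm_pcoa` from [pcoa()].
#' @param metadata optional tibble with `sample` and `group`.
#' @param ... unused.
#' @return A ggplot of the first two axes, annotated with the proportion
#'   of positive inertia each explains.
#' @method autoplot mm_pcoa
#' @export
autoplot.mm_pcoa <- function(object, metadata = NULL, ...) {
  d <- object$coordinates
  if (!is.null(metadata)) d <- left_join(d, metadata, by = "sample")
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i,
                             100 * object$proportion_explained[i])
  p <- ggplot(d, aes(x = .data$axis_1, y = .data$axis_2))
  p <- if ("group" %in% names(d)) {
    p + geom_point(aes(colour = .data$group), size = 2)
  } else {
    p + geom_point(size = 2)
  }
  p + labs(x = lab(1), y = lab(2)) + theme_minimal()
}

#' VIP-versus-significance plot of a differential screen
#'
#' @param screen tibble from [differential_screen()].
#' @param vip_threshold,p_threshold cutoffs to draw as reference lines.
#' @return A ggplot: VIP against -log10 p, selected features highlighted.
#' @export
plot_screen <- function(screen, vip_threshold = 1, p_threshold = 0.05) {
  ggplot(screen, aes(x = .data$vip, y = -log10(.data$p),
                     colour = .data$selected)) +
    geom_point(alpha = 0.7) +
    geom_vline(xintercept = vip_threshold, linetype = 2) +
    geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "VIP", y = expression(-log[10](p)), colour = "selected") +
    theme_minimal()
}

#' Bipartite/tripartite network plot
#'
#' A quick force-directed layout of an `mm_network`, nodes shaped by layer
#' and edges coloured by sign (co-presence vs exclusion).
#'
#' @param object an `mm_network`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mm_network
#' @export
autoplot.mm_network <- function(object, ...) {
  edges <- network_edge_frame(object)
  if (nrow(edges) == 0) {
    return(ggplot() + annotate("text", 0, 0, label = "empty network") +
             theme_void())
  }
  used <- union(edges$source, edges$target)
  nodes <- object$nodes[object$nodes$node %in% used, ]
  g <- igraph::graph_from_data_frame(edges[c("source", "target")],
                                     directed = FALSE,
                                     vertices = nodes$node)
  set.seed(42)  # layout aesthetics only
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(node = nodes$node, type = nodes$type,
                x = xy[, 1], y = xy[, 2])
  seg <- edges |>
    left_join(pos, by = c(source = "node")) |>
    left_join(pos, by = c(target = "node"), suffix = c("", "_t"))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y, xend = .data$x_t,
                     yend = .data$y_t,
                     colour = factor(.data$sign)), alpha = 0.6) +
    geom_point(data = pos, aes(x = .data$x, y = .data$y,
                               shape = .data$type), size = 3) +
    scale_colour_manual(values = c(`-1` = "steelblue", `1` = "firebrick"),
                        name = "sign",
                        labels = c(`-1` = "exclusion", `1` = "co-presence")) +
    theme_void()
}

#' Bridge-metabolite ranking bar chart
#'
#' @param bridges tibble from [rank_bridge_metabolites()].
#' @param top_n how many bridges to show.
#' @return A ggplot of taxon and indicator degree per bridge metabolite.
#' @export
plot_bridge_ranking <- function(bridges, top_n = 10) {
  d <- head(bridges, top_n) |>
    dplyr::select(-"degree") |>
    tidyr::pivot_longer(c("taxon_degree", "indicator_degree"),
                        names_to = "layer", values_to = "degree") |>
    mutate(metabolite = factor(.data$metabolite,
                               levels = rev(head(bridges$metabolite, top_n))))
  ggplot(d, aes(x = .data$metabolite, y = .data$degree,
                fill = .data$layer)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "significant edges", fill = NULL) +
    theme_minimal()
}
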