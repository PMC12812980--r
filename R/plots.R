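#' Plot a per-site trophic assessment
#'
#' Composite TSI by site, coloured by trophic class, with the class boundaries
#' (30, 50, 60, 70) as reference lines.
#'
#' @param object A `trophic_assessment` from [assess_sites()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.trophic_assessment <- function(object, ...) {
  df <- tidy(object)
  df$site_id <- factor(df$site_id, levels = df$site_id[order(df$tsi)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$tsi, colour = .data$label)) +
    ggplot2::geom_hline(yintercept = c(30, 50, 60, 70), linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Composite TSI", colour = "Trophic class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Plot a co-occurrence network
#'
#' Force-directed layout with nodes coloured by kingdom and edges by sign
#' (solid positive, dashed negative).
#'
#' @param object A `cooccurrence_network`.
#' @param seed Layout seed.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cooccurrence_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- with_stage_seed(seed, "layout", igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$taxon_id)
  edges <- dplyr::mutate(object$edges,
    x = nodes$x[pos[.data$taxon_i]], y = nodes$y[pos[.data$taxon_i]],
    xend = nodes$x[pos[.data$taxon_j]], yend = nodes$y[pos[.data$taxon_j]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linetype = .data$sign),
      colour = "grey50", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kingdom), size = 2) +
    ggplot2::scale_linetype_manual(values = c(`+` = "solid", `-` = "dashed")) +
    ggplot2::labs(colour = "Kingdom", linetype = "Edge sign",
                  title = if (!is.na(object$group)) paste("Group", object$group) else NULL) +
    ggplot2::theme_void()
}

#' Plot topology metrics across trophic groups
#'
#' One panel per metric, groups on the x axis in the order supplied, so the
#' cross-gradient trends (e.g. modularity down, negative-edge share up) are
#' visible at a glance.
#'
#' @param comparison Output of [compare_topologies()].
#' @return A ggplot object.
#' @export
plot_topology_trends <- function(comparison) {
  group_cols <- setdiff(names(comparison), c("metric", "delta", "trend"))
  long <- tidyr::pivot_longer(comparison, dplyr::all_of(group_cols),
                              names_to = "group", values_to = "value")
  long$group <- factor(long$group, levels = group_cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value, group = .data$metric)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Trophic group", y = NULL) +
    ggplot2::theme_minimal()
}
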