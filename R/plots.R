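# ggplot2 displays for networks, CV tables and regression summaries.

#' Plot a trait network
#'
#' Nodes on a circle, edges as segments; node size scales with degree and
#' colour with detected module.
#'
#' @param object A `trait_network`.
#' @param method Community method used to colour modules.
#' @param label_size Text size for trait labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_network <- function(object, method = "greedy",
                                   label_size = 3, ...) {
  adj <- object$adjacency
  n <- nrow(adj)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble::tibble(trait = object$trait_names,
                          x = cos(theta), y = sin(theta),
                          degree = rowSums(adj))
  mem <- if (n_edges(object) > 0) network_modules(object, method = method)
         else seq_len(n)
  nodes$module <- factor(mem)
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  edges <- tibble::tibble(x = nodes$x[idx[, 1]], y = nodes$y[idx[, 1]],
                          xend = nodes$x[idx[, 2]], yend = nodes$y[idx[, 2]])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree,
                                     colour = .data$module)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$trait), size = label_size) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = if (!is.na(object$group)) object$group else NULL)
  p
}

#' Bar chart of trait variability ranking
#'
#' @param cvt CV table from [cv_table()].
#' @param mode Ranking convention, see [cv_trait_ranking()].
#' @return A ggplot object.
#' @export
plot_cv_ranking <- function(cvt, mode = "mean_of_groups") {
  rk <- cv_trait_ranking(cvt, mode = mode)
  ggplot2::ggplot(rk, ggplot2::aes(x = stats::reorder(.data$trait, .data$cv),
                                   y = .data$cv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "coefficient of variation") +
    ggplot2::theme_minimal()
}

#' Scatter plots of topology metrics against an environmental variable
#'
#' One panel per topology metric with a least-squares line; the standard
#' display for network-environment relationships across water bodies.
#'
#' @param topo Per-group topology metrics.
#' @param env Environmental table with a `group` column.
#' @param variable Environmental column to plot against.
#' @return A ggplot object.
#' @export
plot_topology_vs_env <- function(topo, env, variable) {
  joined <- dplyr::inner_join(topo, env, by = "group")
  long <- tidyr::pivot_longer(
    joined[, c("group", variable, "edge_density", "avg_path_length",
               "avg_clustering", "modularity")],
    cols = c("edge_density", "avg_path_length", "avg_clustering",
             "modularity"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[variable]],
                                     y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
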