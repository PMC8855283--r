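#' Heatmap of the transition probability matrix
#'
#' Rows are the current state, columns the next state; cell shade encodes
#' the transition probability. Structurally impossible or never-observed
#' transitions are blank. State order follows the state space (pathway
#' modules grouped together), with the start and exit pseudo-states first
#' and last.
#'
#' @param object A `transition_model`.
#' @param min_prob Hide cells below this probability (default 0: show all
#'   observed transitions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_model
#' @export
autoplot.transition_model <- function(object, min_prob = 0, ...) {
  df <- tidy(object) |> dplyr::filter(.data$prob >= min_prob)
  lev <- object$space$all
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$to, levels = lev),
    y = factor(.data$from, levels = rev(lev)),
    fill = .data$prob
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#fff7fb", high = "#08306b",
                                 limits = c(0, 1), name = "TP value") +
    ggplot2::scale_x_discrete(drop = FALSE, position = "top") +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = "to state", y = "from state") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 0, vjust = 0.5))
}

#' Render the transition heatmap to a file
#'
#' @param model A `transition_model`.
#' @param path Output path (extension chooses the device, e.g. `.png`,
#'   `.svg`).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return The path, invisibly.
#' @export
render_heatmap <- function(model, path, width = 8, height = 7, dpi = 150) {
  ggplot2::ggsave(path, autoplot(model), width = width, height = height,
                  dpi = dpi)
  invisible(path)
}

#' Engagement-trail graph of the filtered transition structure
#'
#' Nodes are behavioral states retained by [display_filter()], coloured by
#' trail; node size encodes visit quantity and dwell time (area proportional
#' to `quantity * mean_time`, i.e. total time spent). Edges are the
#' transitions above the display cutoff, with width proportional to the
#' transition probability. The layout is deterministic
#' (Fruchterman-Reingold from a fixed seed).
#'
#' @param filtered Output of [display_filter()].
#' @param summaries Per-state summary from [summarize_states()].
#' @param trail_map State-to-trail mapping (default [default_trail_map()]).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_trail_graph <- function(filtered, summaries,
                             trail_map = default_trail_map(), seed = 42) {
  edges <- filtered$edges
  nodes <- tibble::tibble(state = unique(c(edges$from, edges$to))) |>
    dplyr::left_join(summaries, by = "state") |>
    dplyr::left_join(trail_map, by = "state") |>
    dplyr::mutate(
      trail = dplyr::coalesce(.data$trail, "OTHER"),
      size = sqrt(pmax(dplyr::coalesce(.data$total_time, 0), 1))
    )
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = nodes$state)
  layout <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes$x <- layout[, 1]
  nodes$y <- layout[, 2]
  edges <- edges |>
    dplyr::left_join(nodes[, c("state", "x", "y")],
                     by = c("from" = "state")) |>
    dplyr::left_join(nodes[, c("state", "x", "y")],
                     by = c("to" = "state"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$prob),
      colour = "grey60", alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$trail)
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$state),
      size = 2.7, vjust = -1.2
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), name = "TP value") +
    ggplot2::scale_size(range = c(2, 10), guide = "none") +
    ggplot2::scale_colour_brewer(palette = "Set1", name = "trail") +
    ggplot2::theme_void()
}

#' @rdname plot_trail_graph
#' @param path Output path for the rendered image.
#' @param ... Passed to [ggplot2::ggsave()].
#' @export
render_trail_graph <- function(filtered, summaries, path,
                               trail_map = default_trail_map(), seed = 42,
                               ...) {
  ggplot2::ggsave(path, plot_trail_graph(filtered, summaries, trail_map,
                                         seed),
                  width = 8, height = 6, dpi = 150, ...)
  invisible(path)
}
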