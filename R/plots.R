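#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the comparison graph of a fitted network
#'
#' Nodes are treatments, edges are direct comparisons; edge width scales
#' with the number of studies informing the comparison.
#'
#' @param object An `nma_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nma_fit <- function(object, ...) {
  edges <- object$data |>
    dplyr::count(.data$treat1, .data$treat2, name = "n_studies")
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = object$treatments)
  )
  xy <- igraph::layout_in_circle(g)
  nodes <- tibble::tibble(treat = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  seg <- edges |>
    dplyr::left_join(nodes, by = c(treat1 = "treat")) |>
    dplyr::left_join(nodes, by = c(treat2 = "treat"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$n_studies),
      colour = "grey60"
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                                    label = .data$treat)) +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}

#' Power of the planned trial as a function of the total sample size
#'
#' Draws the closed-form power curve for both analysis plans (with and
#' without the existing network) with the total allocated by
#' [optimal_split()] at each point.
#'
#' @inheritParams ssnma
#' @param n_range Integer vector of total sample sizes to evaluate.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(p1, p2, enma_sigma, n_range = seq(50, 2000, 25),
                             sig.level = 0.05) {
  grid <- purrr::map_dfr(n_range, function(N) {
    al <- optimal_split(p1, p2, N)
    tibble::tibble(
      n_total = N,
      with = design_power(p1, p2, al[["n1"]], al[["n2"]], enma_sigma,
                          "with", sig.level),
      without = design_power(p1, p2, al[["n1"]], al[["n2"]],
                             method = "without", sig.level = sig.level)
    )
  }) |>
    tidyr::pivot_longer(c("with", "without"), names_to = "method",
                        values_to = "power")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$n_total, y = .data$power,
                                     colour = .data$method)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "total sample size", y = "power",
                  colour = "analysis") +
    ggplot2::theme_minimal()
}

#' Plot a simulation summary
#'
#' Side-by-side comparison of simulated and closed-form power by analysis
#' method and allocation strategy, for the output of
#' [simulate_design_fixed_total()] or [simulate_design_target_power()].
#'
#' @param summary A simulation summary tibble.
#' @return A ggplot object.
#' @export
plot_simulation_power <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(c("sim_power", "formula_power"),
                        names_to = "source", values_to = "power") |>
    dplyr::mutate(source = sub("_power$", "", .data$source))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$allocation, y = .data$power,
                                     fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "allocation", y = "power", fill = NULL) +
    ggplot2::theme_minimal()
}
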