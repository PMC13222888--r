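#' Plot a Hasse diagram
#'
#' Layered node-link drawing: elements are placed by level (top level at
#' the top), cover relations drawn as segments, isolated elements shown
#' hollow at the side of their level.
#'
#' @param object A [hasse_diagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hasse_diagram <- function(object, ...) {
  lev <- object$levels
  nodes <- tibble::tibble(element = names(lev), level = as.integer(lev)) |>
    dplyr::group_by(.data$level) |>
    dplyr::mutate(x = seq_along(.data$element) - (dplyr::n() + 1) / 2,
                  isolated = .data$element %in% object$isolated) |>
    dplyr::ungroup()
  edges <- object$covers |>
    dplyr::left_join(nodes, by = c("from" = "element")) |>
    dplyr::left_join(nodes, by = c("to" = "element"), suffix = c("", "_to"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$level))
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$level,
                   xend = .data$x_to, yend = .data$level_to),
      colour = "grey50"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$isolated), size = 9,
                        fill = "white", colour = "grey30") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 22),
                                guide = "none") +
    ggplot2::geom_text(ggplot2::aes(label = .data$element), size = 3) +
    ggplot2::scale_y_continuous(breaks = seq_len(object$L)) +
    ggplot2::labs(y = "level", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a transition matrix as a heatmap
#'
#' @param object A [transition_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$to, y = .data$from,
                                 fill = .data$area_km2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$area_km2, 3)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "to class", y = "from class", fill = "km²") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a change map
#'
#' @param object A [classify_change()] map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.change_map <- function(object, ...) {
  lab <- unclass(object)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lab)), times = ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    label = factor(c(lab), levels = c("stable", "degradation", "restoration",
                                      "other_change", "nodata"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      stable = "grey85", degradation = "firebrick",
      restoration = "forestgreen", other_change = "goldenrod",
      nodata = "white"
    ), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Plot per-unit group influence scores
#'
#' @param object A [group_height_scores()] result.
#' @param ... Unused.
#' @return A ggplot object (units on the y axis, one column per group).
#' @export
autoplot.group_scores <- function(object, ...) {
  tidyr::pivot_longer(tibble::as_tibble(object), -"unit_id",
                      names_to = "group", values_to = "score") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$unit_id,
                                 fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}
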