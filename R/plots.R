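#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a persistence landscape
#'
#' One line per layer over the 256 filtration levels.
#'
#' @param object A `persistence_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.persistence_landscape <- function(object, ...) {
  df <- tibble::tibble(
    level = rep(attr(object, "levels"), each = max(nrow(object), 1L)),
    layer = factor(rep(seq_len(max(nrow(object), 1L)), 256)),
    height = if (nrow(object) > 0) as.numeric(object) else 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$height,
                                   colour = .data$layer)) +
    ggplot2::geom_line(show.legend = nrow(object) <= 12) +
    ggplot2::labs(x = "filtration level", y = "landscape height") +
    ggplot2::theme_minimal()
}

#' Plot a Betti curve
#'
#' @param object A `betti_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.betti_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$level, .data$beta)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "filtration level", y = "Betti number") +
    ggplot2::theme_minimal()
}

#' Plot a persistence diagram
#'
#' Births against deaths, one panel per homology dimension.
#'
#' @param pairs A `persistence_pairs` tibble.
#' @return A ggplot.
#' @export
plot_diagram <- function(pairs) {
  df <- tibble::as_tibble(pairs[, c("dim", "birth", "death", "essential")])
  ggplot2::ggplot(df, ggplot2::aes(.data$birth, .data$death,
                                   shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~dim, labeller = ggplot2::label_both) +
    ggplot2::theme_minimal()
}

#' Plot a feature map or gaze heatmap as a tile grid
#'
#' @param object A `feature_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_map <- function(object, ...) {
  df <- tibble::tibble(
    row = as.integer(row(object)), col = as.integer(col(object)),
    value = as.numeric(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.feature_map
#' @export
autoplot.gaze_heatmap <- function(object, ...) {
  df <- tibble::tibble(
    row = as.integer(row(object)), col = as.integer(col(object)),
    value = as.numeric(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "gaze mass") +
    ggplot2::theme_minimal()
}

#' Plot a weighted ECDF (step function)
#'
#' @param object A `weighted_ecdf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.weighted_ecdf <- function(object, ...) {
  df <- tibble::tibble(value = object$support, cum = object$cum_weight)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$cum)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "feature value", y = "cumulative weight") +
    ggplot2::theme_minimal()
}
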