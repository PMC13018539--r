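raster_df <- function(m, plane) {
  tibble(x = rep(0:(ncol(m) - 1L), each = nrow(m)),
         y = rep(0:(nrow(m) - 1L), times = ncol(m)),
         value = as.numeric(m), plane = plane)
}

#' Plot a slice with its contours
#'
#' Greyscale raster with the annotated or predicted joint contours
#' overlaid (left in red, right in green, the usual radiological display).
#'
#' @param image `H x W` matrix.
#' @param contours A list/collection of `sij_polyline`s, or a contour
#'   tibble with a `contour` list-column.
#' @return A ggplot.
#' @export
plot_slice <- function(image, contours = list()) {
  if (is.data.frame(contours)) contours <- contours$contour
  df <- raster_df(image, "slice")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  for (poly in contours) {
    if (!inherits(poly, "sij_polyline") || !poly$present) next
    p <- p + ggplot2::geom_path(
      data = as_tibble(poly),
      ggplot2::aes(.data$x, .data$y, colour = .data$side),
      inherit.aes = FALSE, linewidth = 0.6)
  }
  p + ggplot2::scale_colour_manual(values = c(left = "red", right = "green3"),
                                   name = NULL)
}

#' @export
autoplot.sij_targets <- function(object, ...) {
  planes <- targets_to_planes(object)
  names8 <- c("left ux", "left uy", "left source", "left sink",
              "right ux", "right uy", "right source", "right sink")
  df <- dplyr::bind_rows(lapply(1:8, function(i) {
    raster_df(planes[, , i], names8[i])
  }))
  df$plane <- factor(df$plane, levels = names8)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~plane, nrow = 2) +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sij_delineator <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$step, .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "step", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sij_classifier <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$step, .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "step", y = "training cross-entropy (per batch)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sij_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "task_id", "auc", "balanced_accuracy",
                  "sensitivity", "specificity"),
    -"task_id", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$task_id, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
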