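# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_errorbar
#'   scale_x_log10 labs theme_minimal facet_wrap
NULL

#' Plot a fitted dose-response curve
#'
#' Mean response per concentration (error bars = SD) with the fitted
#' four-parameter logistic curve on a log-dose axis.
#'
#' @param object A `fourpl_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  per <- object$data
  p <- ggplot(per, aes(x = .data$concentration, y = .data$mean)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  width = 0.05, na.rm = TRUE) +
    geom_point() +
    scale_x_log10() +
    labs(x = "concentration (nM)", y = object$response) +
    theme_minimal()
  if (!is.na(object$ic50)) {
    grid <- tibble(concentration = 10^seq(log10(min(per$concentration)),
                                          log10(max(per$concentration)),
                                          length.out = 200))
    grid$fit <- fourpl_curve(grid$concentration, object$top, object$bottom,
                             object$ic50, object$hill)
    p <- p + geom_line(data = grid, aes(y = .data$fit), colour = "steelblue")
  }
  p
}

#' Plot PCA feature weights
#'
#' @param object A `pca_weighting`.
#' @param ... Ignored.
#' @return A ggplot bar chart of the normalised weights.
#' @export
autoplot.pca_weighting <- function(object, ...) {
  t <- tidy(object)
  ggplot(t, aes(x = stats::reorder(.data$feature, -.data$weight),
                y = .data$weight)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "normalised weight",
         title = sprintf("k = %d component(s) at %.0f%% cumulative variance",
                         object$k, 100 * object$cum_var_threshold)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot composite-metric dose series per compound
#'
#' @param metric_tbl Output of [compute_composite_metric()].
#' @return A ggplot object faceted by cell line and compound.
#' @export
plot_metric_series <- function(metric_tbl) {
  per <- metric_tbl |>
    filter(.data$concentration > 0) |>
    group_by(.data$cell_line, .data$compound, .data$concentration) |>
    summarise(mean = mean(.data$sigma), sd = sd(.data$sigma), .groups = "drop")
  ggplot(per, aes(x = .data$concentration, y = .data$mean)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  width = 0.05, na.rm = TRUE) +
    geom_point() + geom_line() +
    scale_x_log10() +
    facet_wrap(~ .data$cell_line + .data$compound) +
    labs(x = "concentration (nM)", y = "composite metric") +
    theme_minimal()
}

#' Display a spheroid mask over its image
#'
#' @param image Numeric matrix.
#' @param mask A `spheroid_mask`.
#' @return A ggplot raster with the mask boundary overlaid.
#' @export
plot_segmentation <- function(image, mask) {
  df <- tibble(
    x = rep(seq_len(ncol(image)), each = nrow(image)),
    y = rep(seq_len(nrow(image)), times = ncol(image)),
    value = as.vector(image))
  poly <- as_tibble(boundary_polygon(mask))
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(aes(fill = .data$value)) +
    ggplot2::geom_path(data = poly, colour = "red") +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    theme_minimal()
}
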