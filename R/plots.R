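#' Spatial map of a per-cell quantity
#'
#' Scatter of cell centroids colored by a metric (total counts, number of
#' features, predicted expression of one gene, ...), with the color range
#' clipped at the 99th percentile via [clip_percentile()] so outlier cells
#' do not wash out the map.
#'
#' @param coords Tibble/data frame with `x`, `y` centroid columns.
#' @param values Numeric vector, one value per row of `coords`.
#' @param name Legend title.
#' @param clip_p Upper clipping percentile (default 99).
#' @return A ggplot object.
#' @export
plot_spatial_metric <- function(coords, values, name = "value", clip_p = 99) {
  stopifnot(nrow(coords) == length(values))
  rng <- clip_percentile(values, clip_p)
  df <- tibble(x = coords$x, y = coords$y, v = pmin(values, rng[2]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$v)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_viridis_c(name = name, limits = rng) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Training-curve plot for a fitted model
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object showing train/validation loss per epoch with the
#'   best (returned) epoch marked.
#' @export
autoplot.trained_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "training log", subtitle = sprintf(
      "best epoch %d, validation loss %.4f", object$best_epoch, object$best_val_loss))
}

#' Per-gene metric distributions of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object: histograms of per-gene PCC and RMSE.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_gene, c("pcc", "rmse"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(subtitle = sprintf("mean PCC %.3f, mean RMSE %.3f",
                                     object$mean_pcc, object$mean_rmse))
}
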