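#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-unit tibble of a result
#' object, `glance()` a one-row summary.
#'
#' @param x A staincast result object.
#' @param ... Unused.
#' @return A tibble.
#' @name staincast-broom
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname staincast-broom
#' @export
tidy.eval_report <- function(x, ...) x$per_gene

#' @rdname staincast-broom
#' @export
glance.eval_report <- function(x, ...) {
  tibble(n_genes = nrow(x$per_gene), n_excluded = length(x$excluded_genes),
         mean_pcc = x$mean_pcc, mean_rmse = x$mean_rmse,
         binary_accuracy = x$binary_accuracy)
}

#' @rdname staincast-broom
#' @export
tidy.trained_model <- function(x, ...) x$log

#' @rdname staincast-broom
#' @export
glance.trained_model <- function(x, ...) {
  tibble(input_dim = x$input_dim, d_genes = x$d_genes,
         n_parameters = parameter_count(x),
         epochs_run = nrow(x$log), best_epoch = x$best_epoch,
         best_val_loss = x$best_val_loss)
}

#' @rdname staincast-broom
#' @export
tidy.cell_counts <- function(x, ...) x$obs

#' @rdname staincast-broom
#' @export
glance.cell_counts <- function(x, ...) {
  tibble(n_cells = nrow(x$counts), n_genes = ncol(x$counts),
         total_umi = sum(x$obs$total_umi),
         median_umi = median(x$obs$total_umi),
         median_area_px = median(x$obs$area_px))
}

#' @rdname staincast-broom
#' @export
tidy.expression_panel <- function(x, ...) x$stats

#' @rdname staincast-broom
#' @export
tidy.nucleus_polygons <- function(x, ...) {
  tidyr::unnest(
    dplyr::mutate(as_tibble(x),
                  vertices = purrr::map(.data$vertices, as_tibble)),
    "vertices")
}
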