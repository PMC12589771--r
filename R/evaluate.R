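#' Per-gene Pearson correlation between truth and prediction
#'
#' Both matrices are expected in log1p-normalized space. Genes whose truth
#' or prediction vector has zero variance across cells have no defined
#' correlation; they are excluded from the mean and listed.
#'
#' @param y_true,y_pred Cells x genes matrices of equal shape, >= 2 cells.
#' @return List with `per_gene` tibble (`gene`, `pcc`), `mean_pcc`, and
#'   `excluded` (zero-variance gene names).
#' @export
per_gene_pcc <- function(y_true, y_pred) {
  stopifnot(identical(dim(y_true), dim(y_pred)))
  if (nrow(y_true) < 2) abort("need at least 2 cells")
  genes <- colnames(y_true) %||% sprintf("g%d", seq_len(ncol(y_true)))
  s_t <- apply(y_true, 2, sd); s_p <- apply(y_pred, 2, sd)
  ok <- s_t > 0 & s_p > 0
  pcc <- rep(NA_real_, length(genes))
  if (any(ok))
    pcc[ok] <- purrr::map_dbl(which(ok), ~ cor(y_true[, .x], y_pred[, .x]))
  list(per_gene = tibble(gene = genes, pcc = pcc),
       mean_pcc = mean(pcc[ok]),
       excluded = genes[!ok])
}

#' Per-gene root mean square error
#'
#' Per gene, the Euclidean distance between truth and prediction vectors
#' divided by `sqrt(n_cells)` — i.e. `sqrt(mean((y_true - y_pred)^2))`
#' across cells — with the mean over genes as the summary.
#'
#' @inheritParams per_gene_pcc
#' @return List with `per_gene` tibble (`gene`, `rmse`) and `mean_rmse`.
#' @export
per_gene_rmse <- function(y_true, y_pred) {
  stopifnot(identical(dim(y_true), dim(y_pred)))
  genes <- colnames(y_true) %||% sprintf("g%d", seq_len(ncol(y_true)))
  rmse <- sqrt(colMeans((y_true - y_pred)^2))
  list(per_gene = tibble(gene = genes, rmse = unname(rmse)),
       mean_rmse = mean(rmse))
}

#' Binary expressed/silent prediction accuracy
#'
#' Fraction of (cell, gene) entries where the thresholded probability
#' (`p >= threshold` counts as expressed) agrees with the true label.
#'
#' @param b_true Logical (or 0/1) truth matrix.
#' @param p_expressed Probability matrix of the same shape.
#' @param threshold Decision threshold (default 0.5, inclusive).
#' @return Scalar accuracy in `[0, 1]`.
#' @export
binary_accuracy <- function(b_true, p_expressed, threshold = 0.5) {
  stopifnot(identical(dim(as_row(b_true * 1)), dim(as_row(p_expressed))))
  mean((p_expressed >= threshold) == (b_true > 0))
}

#' Assemble a full evaluation report
#'
#' @param y_true,y_pred Cells x genes matrices in log1p space.
#' @param b_true Optional truth labels for the classification accuracy
#'   (default `y_true > 0`).
#' @param p_expressed Optional probability matrix; when missing, binary
#'   accuracy is reported as `NA`.
#' @param threshold Classification threshold.
#' @return An `eval_report`: `per_gene` tibble (`gene`, `pcc`, `rmse`,
#'   `n_cells`), `mean_pcc`, `mean_rmse`, `binary_accuracy`,
#'   `excluded_genes`.
#' @export
eval_report <- function(y_true, y_pred, b_true = y_true > 0,
                        p_expressed = NULL, threshold = 0.5) {
  pcc <- per_gene_pcc(y_true, y_pred)
  rmse <- per_gene_rmse(y_true, y_pred)
  per_gene <- dplyr::left_join(pcc$per_gene, rmse$per_gene, by = "gene")
  per_gene$n_cells <- nrow(y_true)
  acc <- if (!is.null(p_expressed))
    binary_accuracy(b_true, p_expressed, threshold) else NA_real_
  structure(list(per_gene = per_gene, mean_pcc = pcc$mean_pcc,
                 mean_rmse = rmse$mean_rmse, binary_accuracy = acc,
                 excluded_genes = pcc$excluded),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d genes (%d excluded): mean PCC %.3f, mean RMSE %.3f%s\n",
              nrow(x$per_gene), length(x$excluded_genes),
              x$mean_pcc, x$mean_rmse,
              if (is.na(x$binary_accuracy)) ""
              else sprintf(", binary accuracy %.1f%%", 100 * x$binary_accuracy)))
  invisible(x)
}

#' Local/global feature ablation harness
#'
#' Trains three models under identical seeds and configuration — on the
#' fused features `z` (576-dim under defaults), on the local C1 block alone
#' (192) and on the global C2 block alone (384) — and evaluates each on the
#' same held-out cells.
#'
#' @param features A [embed_cells()] result (the C1/C2 split must be intact).
#' @param y Cells x genes normalized label matrix.
#' @param cfg A [model_config()]; its seed drives the train/test split too.
#' @param test_fraction Held-out fraction used for evaluation (default 0.2).
#' @return Tibble with one row per variant: `variant`, `input_dim`,
#'   `mean_pcc`, `mean_rmse`.
#' @export
run_ablation <- function(features, y, cfg = model_config(), test_fraction = 0.2) {
  stopifnot(inherits(features, "histology_features"))
  n <- nrow(features$z)
  test_idx <- withr::with_seed(cfg$seed, sample.int(n, max(2L, round(test_fraction * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  purrr::map_dfr(c("full", "local_only", "global_only"), function(variant) {
    Xv <- feature_slice(features, variant)
    m <- fit(Xv[train_idx, , drop = FALSE], y[train_idx, , drop = FALSE], cfg = cfg)
    pred <- predict_cells(m, Xv[test_idx, , drop = FALSE])
    rep <- eval_report(y[test_idx, , drop = FALSE], pred$y_hat)
    tibble(variant = variant, input_dim = ncol(Xv),
           mean_pcc = rep$mean_pcc, mean_rmse = rep$mean_rmse)
  })
}
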