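#' Export predicted expression as an AnnData .h5ad file
#'
#' The stored `X` is the denormalized prediction `expm1(y_hat)` (the inverse
#' of the log1p transform; predicted cells have no observed library size, so
#' no per-cell total rescaling is applied). The normalized predictions and
#' the expressed probabilities are kept in layers; cell coordinates go to
#' `obs`. With `gate = TRUE`, entries whose expressed probability is below
#' 0.5 are zeroed in `X` — off by default, exposed as an option.
#'
#' @param y_hat Non-negative cells x genes matrix of normalized predictions
#'   (from [predict_cells()]).
#' @param p_expressed Matching probability matrix.
#' @param coords Tibble/data frame with per-cell `x`, `y` (pixel
#'   coordinates); rownames or a `cell_id` column give cell ids.
#' @param panel The [build_panel()] result used in training (gene order
#'   must match `y_hat` columns).
#' @param path Output `.h5ad` path.
#' @param gate Zero out entries with `p_expressed < 0.5` (default FALSE).
#' @param extra_uns Named list merged into `uns` (e.g. config hash, seed).
#' @return `path`, invisibly.
#' @export
export_predictions_h5ad <- function(y_hat, p_expressed, coords, panel, path,
                                    gate = FALSE, extra_uns = list()) {
  stopifnot(identical(dim(y_hat), dim(p_expressed)),
            inherits(panel, "expression_panel"),
            ncol(y_hat) == length(panel$genes), nrow(coords) == nrow(y_hat))
  ids <- coords$cell_id %||% rownames(y_hat) %||% sprintf("cell_%04d", seq_len(nrow(y_hat)))
  X <- expm1(y_hat)
  if (gate) X[p_expressed < 0.5] <- 0
  obs <- data.frame(x = coords$x, y = coords$y, row.names = ids)
  var <- as.data.frame(panel$stats[match(panel$genes, panel$stats$gene),
                                   c("cluster", "p_adj", "log2fc")])
  rownames(var) <- panel$genes
  uns <- c(list(gate = as.integer(gate),
                target_sum = panel$normalization$target_sum %||% NA_real_,
                panel_hash = config_hash(panel$genes)),
           extra_uns)
  dimnames(X) <- list(ids, panel$genes)
  dimnames(y_hat) <- list(ids, panel$genes)
  dimnames(p_expressed) <- list(ids, panel$genes)
  write_h5ad(path, X = X, obs = obs, var = var,
             layers = list(normalized = y_hat, p_expressed = p_expressed),
             uns = uns)
}
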