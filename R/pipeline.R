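#' File-based pipeline commands
#'
#' Thin, idempotent wrappers that chain the package's functions over on-disk
#' artifacts, mirroring the workflow from slide to prediction: `simulate ->
#' prepare -> train -> predict -> evaluate` (plus `ablate`). Every artifact
#' embeds the seed and a configuration hash; [run_evaluate()] refuses to
#' compare artifacts whose gene panels differ. The same commands are exposed
#' from the shell through the `inst/cli/staincast` Rscript.
#'
#' @param out_dir,fixture_dir,prepared_dir Directories for artifacts.
#' @param cfg A [synth_config()] for `run_simulate`.
#' @param seed Integer seed recorded in (and governing) each step.
#' @name staincast-pipeline
NULL

#' @rdname staincast-pipeline
#' @return `run_simulate`: the fixture paths, invisibly.
#' @export
run_simulate <- function(out_dir, cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  slide <- simulate_slide(cfg)
  write_fixture(slide, out_dir)
}

#' @rdname staincast-pipeline
#' @param backbone_name `"toy"` (the deterministic statistics backbone) or
#'   an [backbone()] object supplied programmatically.
#' @param qc Named list overriding [qc_filter()] thresholds
#'   (`max_area`, `min_umi`, `max_mito`).
#' @param panel_thresholds Named list overriding [build_panel()] thresholds
#'   (`p_adj_max`, `min_abs_log2fc`).
#' @param target_sum Normalization target passed to [normalize_log1p()].
#' @param n_top_hvg,resolution,n_pcs,min_cluster_size Panel-selection
#'   controls (see [select_hvg()], [cluster_cells()]).
#' @return `run_prepare`: path of the written `cells.h5ad`, invisibly.
#' @export
run_prepare <- function(fixture_dir, out_dir, backbone_name = "toy",
                        qc = list(), panel_thresholds = list(),
                        target_sum = 1e4, n_top_hvg = 2000L,
                        resolution = 0.6, n_pcs = 50L,
                        min_cluster_size = 0L, seed = 0L) {
  fx <- read_fixture(fixture_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  image <- rescale_to_target(fx$image, 0.5)
  polygons <- segment_nuclei(image, engine_replay(fx$polygons))
  cells <- aggregate_bins_to_cells(fx$bins, polygons)
  cells <- do.call(qc_filter, c(list(cells), qc))
  if (nrow(cells$counts) == 0) abort("no cells pass QC")
  norm <- normalize_log1p(cells, target_sum = target_sum)

  hvg <- select_hvg(norm, n_top = n_top_hvg)
  labels <- cluster_cells(norm[, hvg, drop = FALSE], n_pcs = n_pcs,
                          resolution = resolution,
                          min_cluster_size = min_cluster_size, seed = seed)
  stats <- rank_genes_wilcoxon(norm, labels)
  panel <- do.call(build_panel, c(list(stats), panel_thresholds,
                                  list(normalization = list(target_sum = target_sum,
                                                            log1p = TRUE))))

  bb <- if (inherits(backbone_name, "sc_backbone")) backbone_name else backbone_toy()
  keep <- polygons[match(cells$obs$cell_id, polygons$cell_id), ]
  class(keep) <- class(polygons)
  feats <- embed_cells(image, keep, bb)

  path <- file.path(out_dir, "cells.h5ad")
  write_h5ad(path,
             X = cells$counts,
             obs = as.data.frame(cbind(cells$obs[-1],
                                       x = keep$centroid_x, y = keep$centroid_y,
                                       cluster = labels),
                                 row.names = cells$obs$cell_id),
             var = data.frame(row.names = colnames(cells$counts)),
             layers = list(lognorm = norm),
             obsm = list(X_histology = unname(feats$z)),
             uns = list(seed = seed, target_sum = target_sum,
                        d_local = feats$d_local, d_global = feats$d_global,
                        backbone = feats$backbone,
                        panel_genes = panel$genes,
                        panel_hash = config_hash(panel$genes)))
  utils::write.csv(panel$stats, file.path(out_dir, "panel.csv"), row.names = FALSE)
  saveRDS(panel, file.path(out_dir, "panel.rds"))
  invisible(path)
}

read_prepared <- function(prepared_dir) {
  ad <- read_h5ad(file.path(prepared_dir, "cells.h5ad"))
  panel <- readRDS(file.path(prepared_dir, "panel.rds"))
  feats <- structure(list(z = ad$obsm$X_histology,
                          d_local = as.integer(ad$uns$d_local),
                          d_global = as.integer(ad$uns$d_global),
                          backbone = as.character(ad$uns$backbone),
                          cells = tibble(cell_id = rownames(ad$obs),
                                         x = ad$obs$x, y = ad$obs$y)),
                     class = "histology_features")
  rownames(feats$z) <- rownames(ad$obs)
  list(ad = ad, panel = panel, features = feats)
}

#' @rdname staincast-pipeline
#' @param model_cfg A [model_config()] for training.
#' @return `run_train`: path of the written checkpoint, invisibly.
#' @export
run_train <- function(prepared_dir, out_dir, model_cfg = model_config(),
                      seed = NULL) {
  if (!is.null(seed)) model_cfg$seed <- as.integer(seed)
  pr <- read_prepared(prepared_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  y <- pr$ad$layers$lognorm[, pr$panel$genes, drop = FALSE]
  model <- fit(pr$features, y, cfg = model_cfg, panel = pr$panel)
  model$backbone <- pr$features$backbone
  model$config_hash <- config_hash(unclass(model_cfg))
  path <- file.path(out_dir, "checkpoint.rds")
  saveRDS(model, path)
  utils::write.csv(model$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname staincast-pipeline
#' @param checkpoint Path to a `run_train` checkpoint.
#' @param out_path Output `.h5ad` path.
#' @param gate Zero predictions with expressed probability < 0.5.
#' @return `run_predict`: `out_path`, invisibly.
#' @export
run_predict <- function(checkpoint, prepared_dir, out_path, gate = FALSE) {
  model <- readRDS(checkpoint)
  pr <- read_prepared(prepared_dir)
  if (!identical(model$backbone, pr$features$backbone))
    abort(sprintf("checkpoint backbone '%s' does not match prepared features '%s'",
                  model$backbone, pr$features$backbone))
  pred <- predict_cells(model, pr$features)
  export_predictions_h5ad(pred$y_hat, pred$p_expressed, pr$features$cells,
                          model$panel, out_path, gate = gate,
                          extra_uns = list(seed = model$config$seed,
                                           config_hash = model$config_hash))
}

#' @rdname staincast-pipeline
#' @param prediction_h5ad Path of a `run_predict` output.
#' @param truth_prepared_dir Prepared directory holding the ground-truth
#'   labels (its `lognorm` layer restricted to the panel genes).
#' @return `run_evaluate`: the [eval_report()], invisibly; per-gene CSV and
#'   a JSON summary are written next to the prediction.
#' @export
run_evaluate <- function(prediction_h5ad, truth_prepared_dir,
                         out_dir = dirname(prediction_h5ad)) {
  pred <- read_h5ad(prediction_h5ad)
  pr <- read_prepared(truth_prepared_dir)
  if (!identical(rownames(pred$var), pr$panel$genes))
    abort("prediction and ground-truth artifacts use different gene panels")
  common <- intersect(rownames(pred$obs), rownames(pr$ad$obs))
  if (length(common) < 2) abort("fewer than 2 cells shared between artifacts")
  y_true <- pr$ad$layers$lognorm[common, pr$panel$genes, drop = FALSE]
  rep <- eval_report(y_true,
                     pred$layers$normalized[common, , drop = FALSE],
                     p_expressed = pred$layers$p_expressed[common, , drop = FALSE])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$per_gene, file.path(out_dir, "per_gene_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(glance(rep)), file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rep)
}

#' @rdname staincast-pipeline
#' @return `run_ablate`: the ablation tibble, invisibly; also written as CSV.
#' @export
run_ablate <- function(prepared_dir, out_dir, model_cfg = model_config(),
                       seed = NULL) {
  if (!is.null(seed)) model_cfg$seed <- as.integer(seed)
  pr <- read_prepared(prepared_dir)
  y <- pr$ad$layers$lognorm[, pr$panel$genes, drop = FALSE]
  tab <- run_ablation(pr$features, y, cfg = model_cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "ablation.csv"), row.names = FALSE)
  invisible(tab)
}
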