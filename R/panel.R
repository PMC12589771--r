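#' Select highly variable genes by normalized dispersion
#'
#' Dispersion-based ranking on normalized data: per gene, mean and
#' dispersion (variance / mean) are computed on the de-logged values
#' (`expm1` of the log1p matrix), genes are binned into 20 equal-frequency
#' bins by mean, and the dispersion is z-scored within each bin. The top
#' `n_top` genes by normalized dispersion are returned in original gene
#' order. Constant genes (zero variance) never qualify; if fewer than
#' `n_top` variable genes exist, all of them are returned with a warning.
#'
#' @param norm_matrix Cells x genes matrix from [normalize_log1p()].
#' @param n_top Number of genes to select (default 2000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of selected gene names (original order), with
#'   the per-gene statistics tibble in attribute `"hvg_stats"`.
#' @export
select_hvg <- function(norm_matrix, n_top = 2000L, n_bins = 20L) {
  stopifnot(is.matrix(norm_matrix), !is.null(colnames(norm_matrix)))
  x <- expm1(norm_matrix)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nonconst <- v > 0
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    s <- sd(disp[sel])
    if (is.finite(s) && s > 0) {
      z[sel] <- (disp[sel] - mean(disp[sel])) / s
    } else {
      # singleton or spread-free bin: score against the dispersion itself,
      # giving a neutral z of 1 for any positive dispersion
      z[sel] <- ifelse(disp[sel] > 0, 1, 0)
    }
  }
  z[!nonconst] <- -Inf
  n_avail <- sum(nonconst)
  if (n_avail < n_top) {
    warn(sprintf("only %d genes with nonzero variance (< n_top = %d); returning all",
                 n_avail, n_top))
    n_top <- n_avail
  }
  chosen <- colnames(norm_matrix)[rank(-z, ties.method = "first") <= n_top]
  stats <- tibble(gene = colnames(norm_matrix), mean = mu, dispersion = disp,
                  dispersion_norm = z, selected = colnames(norm_matrix) %in% chosen)
  structure(chosen, hvg_stats = stats)
}

#' Cluster cells by Leiden community detection in PCA space
#'
#' Gene-centered normalized data are projected onto the top `n_pcs`
#' principal components, a k-nearest-neighbor graph is built on Euclidean
#' distances in that space, and Leiden community detection (modularity
#' objective) is run at the given resolution with a fixed seed. Cells in
#' clusters smaller than `min_cluster_size` are labeled `"filtered"` —
#' on real slides such micro-clusters are typically mis-segmented tiles.
#'
#' @param norm_matrix Cells x genes matrix from [normalize_log1p()].
#' @param n_pcs Number of principal components (default 50; capped with a
#'   warning when it exceeds what the data support).
#' @param resolution Leiden resolution (default 0.6).
#' @param min_cluster_size Minimum retained cluster size (default 0 = keep all).
#' @param neighbors_k Neighbors per cell in the kNN graph (default 15).
#' @param seed Integer seed for the Leiden refinement.
#' @return Character vector of per-cell cluster labels ("0", "1", ... by
#'   decreasing cluster size, or "filtered").
#' @export
cluster_cells <- function(norm_matrix, n_pcs = 50L, resolution = 0.6,
                          min_cluster_size = 0L, neighbors_k = 15L, seed = 0L) {
  n <- nrow(norm_matrix)
  if (n < neighbors_k + 1)
    abort(sprintf("need at least neighbors_k + 1 = %d cells", neighbors_k + 1))
  max_pcs <- min(n - 1L, ncol(norm_matrix))
  if (n_pcs > max_pcs) {
    warn(sprintf("n_pcs = %d exceeds data rank; capped at %d", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pcs <- prcomp(norm_matrix, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(neighbors_k)]))
  edges <- cbind(rep(seq_len(n), each = neighbors_k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- withr::with_seed(seed, igraph::membership(
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 3)))
  # relabel by decreasing size for stable, readable labels
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(as.character(seq_along(sizes) - 1L), names(sizes))
  labels <- unname(relabel[as.character(memb)])
  small <- names(table(labels))[table(labels) < min_cluster_size]
  labels[labels %in% small] <- "filtered"
  labels
}

# tie-corrected normal-approximation rank-sum p for one gene given
# precomputed ranks over all cells; ties via the tie term of the variance
wilcoxon_z <- function(values, in_group) {
  n <- length(values); n1 <- sum(in_group); n2 <- n - n1
  r <- rank(values)
  w <- sum(r[in_group]) - n1 * (n1 + 1) / 2          # Mann-Whitney U
  mu <- n1 * n2 / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  # continuity correction toward the mean, as in stats::wilcox.test
  (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
}

#' One-vs-rest Wilcoxon rank-sum marker statistics
#'
#' For every cluster and gene, tests the cluster's cells against all other
#' cells with the Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction), adjusts p-values by Benjamini-Hochberg across
#' genes within each cluster, and reports the log2 fold change of de-logged
#' group means: `log2((mean(expm1(in)) + 1e-9) / (mean(expm1(rest)) + 1e-9))`.
#' Genes constant across all cells get `p = 1` and `log2fc = 0`.
#'
#' @param norm_matrix Cells x genes matrix from [normalize_log1p()].
#' @param labels Per-cell cluster labels; cells labeled `"filtered"` are
#'   dropped before testing.
#' @return Tibble with columns `cluster`, `gene`, `p`, `p_adj`, `log2fc`.
#' @export
rank_genes_wilcoxon <- function(norm_matrix, labels) {
  stopifnot(nrow(norm_matrix) == length(labels))
  keep <- labels != "filtered"
  m <- norm_matrix[keep, , drop = FALSE]
  labels <- labels[keep]
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) abort("need at least 2 clusters")
  if (any(table(labels) < 2)) abort("every cluster needs at least 2 cells")
  ex <- expm1(m)
  out <- purrr::map_dfr(clusters, function(cl) {
    ing <- labels == cl
    p <- apply(m, 2, function(v) {
      if (max(v) == min(v)) return(1)
      2 * pnorm(-abs(wilcoxon_z(v, ing)))
    })
    p <- unname(p)
    mu_in <- unname(colMeans(ex[ing, , drop = FALSE]))
    mu_out <- unname(colMeans(ex[!ing, , drop = FALSE]))
    tibble(cluster = cl, gene = colnames(m), p = pmin(p, 1),
           p_adj = p.adjust(pmin(p, 1), method = "BH"),
           log2fc = ifelse(apply(m, 2, function(v) max(v) == min(v)), 0,
                           log2((mu_in + 1e-9) / (mu_out + 1e-9))))
  })
  out
}

#' Assemble the trainable gene panel from marker statistics
#'
#' A gene enters the panel iff in at least one cluster it is significant
#' (`p_adj < p_adj_max`, strict) with `|log2fc| >= min_abs_log2fc`.
#' The panel is deduplicated, keeps the genes' original order of first
#' appearance, and records the thresholds and per-gene best statistics.
#'
#' @param stats Tibble from [rank_genes_wilcoxon()].
#' @param p_adj_max Adjusted-p threshold (default 0.01, strict `<`).
#' @param min_abs_log2fc Absolute log2 fold-change threshold (default 1,
#'   inclusive `>=`).
#' @param normalization Optional normalization metadata to carry (a list,
#'   e.g. `list(target_sum = 1e4, log1p = TRUE)`).
#' @return An `expression_panel`: list with `genes`, `stats` (one row per
#'   panel gene: its best-supporting cluster), `thresholds`, `normalization`.
#' @export
build_panel <- function(stats, p_adj_max = 0.01, min_abs_log2fc = 1.0,
                        normalization = list(target_sum = 1e4, log1p = TRUE)) {
  ok <- stats$p_adj < p_adj_max & abs(stats$log2fc) >= min_abs_log2fc
  hits <- stats[ok, , drop = FALSE]
  if (nrow(hits) == 0)
    abort("no genes pass the panel thresholds; relax p_adj_max / min_abs_log2fc")
  best <- hits |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_min(.data$p_adj, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  genes <- unique(hits$gene)
  best <- best[match(genes, best$gene), ]
  structure(list(genes = genes, stats = best,
                 thresholds = list(p_adj_max = p_adj_max,
                                   min_abs_log2fc = min_abs_log2fc),
                 normalization = normalization),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d genes (p_adj < %g, |log2FC| >= %g)\n",
              length(x$genes), x$thresholds$p_adj_max, x$thresholds$min_abs_log2fc))
  invisible(x)
}

#' Binary expressed/silent labels
#'
#' The classification target of the dual-loss model: a (cell, gene) entry is
#' positive iff its normalized expression is strictly positive (log1p
#' preserves positivity, so this equals `raw count > 0`).
#'
#' @param y Non-negative cells x genes matrix of normalized expression.
#' @return Logical matrix of the same shape.
#' @export
binary_labels <- function(y) {
  if (any(y < 0)) abort("normalized expression must be non-negative")
  y > 0
}

#' Per-cell quality metrics
#'
#' @param m Cells x genes matrix (counts or normalized).
#' @return Tibble with `cell_id` (rownames or index), `total_counts`,
#'   `n_features` (number of nonzero genes).
#' @export
qc_metrics <- function(m) {
  tibble(cell_id = rownames(m) %||% as.character(seq_len(nrow(m))),
         total_counts = unname(Matrix::rowSums(m)),
         n_features = unname(Matrix::rowSums(m > 0)))
}

#' Display range clipped at an upper percentile
#'
#' Color ranges for spatial QC maps are clipped at the p-th percentile so a
#' few extreme cells do not wash out the map.
#'
#' @param values Numeric vector.
#' @param p Upper percentile (default 99).
#' @return `c(0, p-th percentile)`.
#' @export
clip_percentile <- function(values, p = 99) {
  c(0, unname(quantile(values, p / 100, names = FALSE)))
}
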