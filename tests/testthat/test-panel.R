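norm_fixture <- function() {
  sl <- medium_slide()
  cells <- qc_filter(aggregate_bins_to_cells(sl$bins, sl$polygons))
  list(norm = normalize_log1p(cells), cells = cells, slide = sl)
}

test_that("a dominant-dispersion gene is always selected and sizes saturate", {
  withr::with_seed(10, {
    m <- matrix(rpois(200 * 30, 5), 200, 30,
                dimnames = list(NULL, sprintf("g%02d", 1:30)))
    # same mean as its bin mates, far higher dispersion
    m[, 7] <- rpois(200, 5) * rbinom(200, 1, 0.5) * 2
    norm <- log1p(m / rowSums(m) * 1e4)
    colnames(norm) <- colnames(m)
    # 5 mean-bins: the default 20 makes nearly every bin a singleton at
    # 30 genes, which voids within-bin z-scores
    sel <- select_hvg(norm, n_top = 5, n_bins = 5)
    expect_true("g07" %in% sel)
    expect_length(sel, 5)
    # saturation: n_top beyond the number of variable genes returns them all
    expect_warning(all_sel <- select_hvg(norm, n_top = 100), "nonzero variance")
    expect_length(all_sel, 30)
  })
})

test_that("selected genes come back in original column order", {
  withr::with_seed(11, {
    m <- matrix(rpois(100 * 20, 10), 100, 20,
                dimnames = list(NULL, sprintf("g%02d", 1:20)))
    sel <- select_hvg(log1p(m), n_top = 10)
    expect_identical(sel[order(match(sel, colnames(m)))], as.character(sel))
  })
})

test_that("Leiden clustering is deterministic and saturates to filtered", {
  fx <- norm_fixture()
  l1 <- cluster_cells(fx$norm, n_pcs = 20, seed = 3)
  l2 <- cluster_cells(fx$norm, n_pcs = 20, seed = 3)
  expect_identical(l1, l2)
  all_f <- cluster_cells(fx$norm, n_pcs = 20, seed = 3,
                         min_cluster_size = nrow(fx$norm) + 1)
  expect_true(all(all_f == "filtered"))
  expect_warning(cluster_cells(fx$norm, n_pcs = 1000, seed = 3), "capped")
  expect_error(cluster_cells(fx$norm[1:5, ], neighbors_k = 15), "cells")
})

test_that("well-separated morphology-linked programs are recovered (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  sl <- cached_slide("recovery", synth_config(
    image_size_px = c(1536L, 1536L), n_cells = 400L, n_genes = 100L,
    n_programs = 2L, morphology_effect = 2, seed = 3L))
  cells <- qc_filter(aggregate_bins_to_cells(sl$bins, sl$polygons))
  norm <- normalize_log1p(cells)
  # resolution 0.3: with two programs the modularity objective at finer
  # resolutions splits the continuous morphology gradient into sub-clusters
  labels <- cluster_cells(norm, n_pcs = 30, resolution = 0.3, seed = 0)
  truth <- sl$truth$cells$program[match(cells$obs$cell_id, sl$truth$cells$cell_id)]
  expect_gte(length(unique(labels)), 2)
  expect_gte(mclust::adjustedRandIndex(labels, truth), 0.9)
})

test_that("rank-sum p-values match stats::wilcox.test", {
  withr::with_seed(12, {
    m <- matrix(c(rpois(40, 3), rpois(40, 6)), 20, 4,
                dimnames = list(NULL, sprintf("g%d", 1:4)))
    labels <- rep(c("0", "1"), each = 10)
    ours <- rank_genes_wilcoxon(log1p(m), labels)
    for (g in colnames(m)) {
      ref <- suppressWarnings(
        stats::wilcox.test(m[labels == "0", g], m[labels == "1", g],
                           exact = FALSE, correct = TRUE))$p.value
      expect_equal(ours$p[ours$cluster == "0" & ours$gene == g], ref,
                   tolerance = 1e-10)
    }
  })
})

test_that("the normal-approximation p tracks exhaustive enumeration at 4 + 4", {
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(6.3, 7.1, 8.0, 6.6)
  m <- matrix(c(x, y), 8, 1, dimnames = list(NULL, "g"))
  stats <- rank_genes_wilcoxon(log1p(m), rep(c("a", "b"), each = 4))
  p_exact <- exact_wilcoxon_p(x, y)
  expect_lt(abs(stats$p[stats$cluster == "a"] - p_exact), 0.02)
})

test_that("constant genes give p = 1 and log2FC = 0; BH is monotone and >= raw", {
  withr::with_seed(13, {
    m <- matrix(rpois(60 * 6, 4), 60, 6, dimnames = list(NULL, sprintf("g%d", 1:6)))
    m[, 3] <- 2                                           # constant gene
    stats <- rank_genes_wilcoxon(log1p(m), rep(c("0", "1"), each = 30))
    g3 <- stats[stats$gene == "g3", ]
    expect_true(all(g3$p == 1))
    expect_true(all(g3$log2fc == 0))
    one <- stats[stats$cluster == "0", ]
    expect_true(all(one$p_adj >= one$p - 1e-15))
    ord <- order(one$p)
    expect_true(all(diff(one$p_adj[ord]) >= -1e-12))
  })
})

test_that("label-permuted data give uniform-ish p-values", {
  sl <- cached_slide("recovery", synth_config(
    image_size_px = c(1536L, 1536L), n_cells = 400L, n_genes = 100L,
    n_programs = 2L, morphology_effect = 2, seed = 3L))
  norm <- normalize_log1p(qc_filter(aggregate_bins_to_cells(sl$bins, sl$polygons)))
  labels <- withr::with_seed(20, sample(rep(c("a", "b"), length.out = nrow(norm))))
  stats <- rank_genes_wilcoxon(norm, labels)
  p <- stats$p[stats$cluster == "a" & stats$p < 1]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("panel thresholds are strict/inclusive exactly as recorded", {
  stats <- tibble::tibble(
    cluster = c("0", "0", "0", "1", "1"),
    gene = c("g1", "g2", "g3", "g1", "g4"),
    p = rep(0.001, 5),
    p_adj = c(0.01, 0.005, 0.005, 0.001, 0.002),  # g1@0: exactly 0.01 -> fails there
    log2fc = c(2, 1, 0.5, -1, 3))                  # |log2fc| = 1 exactly -> passes
  panel <- build_panel(stats)
  # g1 passes via cluster 1 (p_adj 0.001, |fc| = 1), g2 passes, g3 fails fc,
  # g4 passes: union of qualifying genes across clusters, deduplicated
  expect_setequal(panel$genes, c("g1", "g2", "g4"))
  expect_equal(length(panel$genes), 3)

  none <- dplyr::mutate(stats, p_adj = 0.5)
  expect_error(build_panel(none), "relax")
})

test_that("binary labels flag exactly the positive entries", {
  expect_false(any(binary_labels(matrix(0, 3, 2))))
  expect_identical(unname(binary_labels(matrix(c(0, 0.3, 0), 1))),
                   matrix(c(FALSE, TRUE, FALSE), 1))
  sl <- small_slide()
  cells <- qc_filter(aggregate_bins_to_cells(sl$bins, sl$polygons))
  norm <- normalize_log1p(cells)
  expect_identical(unname(binary_labels(norm)),
                   unname(as.matrix(cells$counts > 0)))
})

test_that("qc metrics and clipping behave on constructed matrices", {
  m <- matrix(c(0, 0, 0, 1, 2, 0, 3, 0, 4), 3, 3, byrow = TRUE,
              dimnames = list(c("empty", "b", "c"), NULL))
  qm <- qc_metrics(m)
  expect_equal(qm$total_counts, c(0, 3, 7))
  expect_equal(qm$n_features, c(0, 2, 2))
  expect_equal(clip_percentile(rep(5, 10)), c(0, 5))
  expect_equal(clip_percentile(0:100, p = 99), c(0, 99))
})
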