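#' Construct a per-cell counts object
#'
#' @param counts Sparse (or dense) non-negative integer cells x genes matrix
#'   with cell ids as rownames and gene names as colnames.
#' @param area_px Per-cell nucleus area in squared pixels.
#' @param mito_regex Case-insensitive regex identifying mitochondrial genes
#'   by name (default the `mt-` prefix; use `"^MT-"` semantics come free from
#'   case folding).
#' @return A `cell_counts` object: the matrix plus an `obs` tibble with
#'   `cell_id`, `area_px`, `total_umi`, `mito_frac`.
#' @export
cell_counts <- function(counts, area_px, mito_regex = "^mt-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            length(area_px) == nrow(counts))
  if (any(counts@x < 0)) abort("counts must be non-negative")
  total <- Matrix::rowSums(counts)
  mito <- grepl(mito_regex, colnames(counts), ignore.case = TRUE)
  mito_counts <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else rep(0, nrow(counts))
  obs <- tibble(cell_id = rownames(counts), area_px = as.numeric(area_px),
                total_umi = as.integer(total),
                mito_frac = mito_counts / pmax(total, 1))
  structure(list(counts = counts, obs = obs), class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d cells x %d genes, median UMI %d\n",
              nrow(x$counts), ncol(x$counts), as.integer(median(x$obs$total_umi))))
  invisible(x)
}

#' Aggregate 2-um bin counts into per-nucleus counts
#'
#' A bin is assigned to a nucleus iff its center lies inside the nucleus
#' polygon (boundary counts as inside). Assignment is exclusive: when
#' polygons overlap, the first polygon in input order wins, so no UMI is
#' counted twice. Per-cell counts are the column sums of the assigned bins'
#' rows; nuclei containing no bin centers get all-zero rows.
#'
#' @param bins A [bin_table()].
#' @param polygons A [nucleus_polygons()] tibble in the same pixel frame.
#' @param mito_regex Passed to [cell_counts()].
#' @return A [cell_counts()] object, one row per polygon, in polygon order.
#' @export
aggregate_bins_to_cells <- function(bins, polygons, mito_regex = "^mt-") {
  stopifnot(inherits(bins, "bin_table"), inherits(polygons, "nucleus_polygons"))
  n_bins <- nrow(bins$counts)
  assignment <- rep(NA_integer_, n_bins)
  bx <- bins$bin_centers$x; by <- bins$bin_centers$y
  for (k in seq_len(nrow(polygons))) {
    v <- polygons$vertices[[k]]
    cand <- which(is.na(assignment) &
                    bx >= min(v[, 1]) - 1e-9 & bx <= max(v[, 1]) + 1e-9 &
                    by >= min(v[, 2]) - 1e-9 & by <= max(v[, 2]) + 1e-9)
    if (length(cand) == 0) next
    hit <- cand[point_in_polygon(bx[cand], by[cand], v[, 1], v[, 2])]
    assignment[hit] <- k
  }
  if (nrow(polygons) > 0 && mean(is.na(assignment)) > 0.99 && n_bins > 0)
    warn("more than 99% of bins fall in no polygon; bin and polygon frames may be mismatched")
  assigned <- which(!is.na(assignment))
  # cells x bins indicator, then counts_cells = indicator %*% counts_bins
  ind <- Matrix::sparseMatrix(i = assignment[assigned], j = assigned, x = 1,
                              dims = c(nrow(polygons), n_bins))
  m <- methods::as(ind %*% bins$counts, "CsparseMatrix")
  dimnames(m) <- list(polygons$cell_id, colnames(bins$counts))
  cell_counts(m, polygons$area_px, mito_regex = mito_regex)
}

#' Quality-control filter for segmented cells
#'
#' Keeps a cell iff all three predicates hold, each strict: nucleus area
#' below `max_area` (oversized nuclei are likely multi-cell aggregates), UMI
#' count strictly above `min_umi` (near-empty regions are likely non-nuclear),
#' and mitochondrial fraction strictly below `max_mito`. Cell order is
#' preserved; an empty result is valid.
#'
#' @param cells A [cell_counts()] object.
#' @param max_area Area threshold in squared pixels at the 0.5 um/px working
#'   scale (default 2000 px^2 = 500 um^2).
#' @param min_umi UMI threshold (default 20; a cell needs > 20 UMIs).
#' @param max_mito Mitochondrial fraction threshold (default 0.15).
#' @return The filtered `cell_counts`.
#' @export
qc_filter <- function(cells, max_area = 2000, min_umi = 20L, max_mito = 0.15) {
  stopifnot(inherits(cells, "cell_counts"),
            max_area > 0, min_umi > 0, max_mito > 0)
  keep <- cells$obs$area_px < max_area &
    cells$obs$total_umi > min_umi &
    cells$obs$mito_frac < max_mito
  structure(list(counts = cells$counts[keep, , drop = FALSE],
                 obs = cells$obs[keep, , drop = FALSE]),
            class = "cell_counts")
}

#' Total-count normalization followed by log1p
#'
#' Scales each cell to `target_sum` total counts and applies `log(1 + x)`:
#' `value = log(1 + count * target_sum / total_umi)`. Zeros map to zeros.
#' Cells with zero totals are an error (run [qc_filter()] first).
#'
#' @param cells A [cell_counts()] object.
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return A dense cells x genes matrix of normalized values with attributes
#'   `target_sum` and `log1p = TRUE` (the normalization metadata recorded in
#'   panels and trained models).
#' @export
normalize_log1p <- function(cells, target_sum = 1e4) {
  stopifnot(inherits(cells, "cell_counts"), target_sum > 0)
  tot <- cells$obs$total_umi
  if (any(tot == 0))
    abort(sprintf("cell(s) with zero total counts: %s",
                  paste(head(cells$obs$cell_id[tot == 0], 5), collapse = ", ")))
  m <- as.matrix(cells$counts)
  m <- log1p(m * (target_sum / tot))
  attr(m, "target_sum") <- target_sum
  attr(m, "log1p") <- TRUE
  m
}
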