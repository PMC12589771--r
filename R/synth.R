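#' Configuration for the synthetic slide generator
#'
#' The generator emulates the statistical structure the pipeline assumes in
#' real data: sparse non-negative integer counts on a 2-um bin grid, nucleus
#' polygons whose observable morphology (size, stain intensity, local
#' density) is linked to per-cell expression programs with zero inflation,
#' and an H&E-like RGB rendering (dark hematoxylin nuclei on a pink eosin
#' background). Default rates are calibrated so that roughly 40% of
#' (cell, gene) count entries are zero while the image-predictable share of
#' per-gene variance stays substantial (see the methods vignette).
#'
#' Cells belong to one of `n_programs` latent programs. Each program has a
#' marker-gene block (8-fold elevated over baseline) and a distinct
#' morphology (base nucleus radius and stain level), so program identity is
#' visible both in expression and in the image — total-count normalization
#' cancels any per-cell scalar, so without a morphology-program link
#' image-based prediction of relative expression would be impossible by
#' construction.
#'
#' @param image_size_px `c(rows, cols)`, both > 256.
#' @param um_per_px Physical scale of the rendered image (default 0.5, the
#'   working scale; 2-um bins are then 4 px).
#' @param n_cells Number of nuclei (>= 1).
#' @param n_genes Number of genes (>= 2); the first three are named with the
#'   mitochondrial `mt-` prefix so QC filters are exercisable.
#' @param n_programs Number of latent cell programs.
#' @param zero_rate Per-(cell, gene) silencing probability in `[0, 1)`.
#' @param count_mean Mean UMI count of an expressed gene at baseline
#'   expected expression 1.
#' @param morphology_effect Strength (>= 0) of the multiplicative link from
#'   standardized nucleus features to expected expression.
#' @param seed Integer seed; the single entropy source for the generator.
#' @return A `synth_config` list.
#' @export
synth_config <- function(image_size_px = c(768L, 768L), um_per_px = 0.5,
                         n_cells = 80L, n_genes = 60L, n_programs = 3L,
                         zero_rate = 0.3, count_mean = 5, morphology_effect = 1.5,
                         seed = 1L) {
  cfg <- list(image_size_px = as.integer(image_size_px), um_per_px = um_per_px,
              n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_programs = as.integer(n_programs), zero_rate = zero_rate,
              count_mean = count_mean, morphology_effect = morphology_effect,
              seed = as.integer(seed))
  if (length(cfg$image_size_px) != 2 || any(cfg$image_size_px <= 256))
    abort("image_size_px must be two values, both > 256")
  if (cfg$n_cells < 1) abort("n_cells must be >= 1")
  if (cfg$n_genes < 2) abort("n_genes must be >= 2")
  if (cfg$zero_rate < 0 || cfg$zero_rate >= 1) abort("need 0 <= zero_rate < 1")
  if (cfg$count_mean <= 0) abort("count_mean must be positive")
  if (cfg$morphology_effect < 0) abort("morphology_effect must be >= 0")
  if (cfg$um_per_px <= 0) abort("um_per_px must be positive")
  structure(cfg, class = "synth_config")
}

#' Build a 2-um bin table
#'
#' @param counts Sparse non-negative integer bins x genes matrix.
#' @param bin_centers Tibble with `barcode`, `x`, `y` (pixel coordinates of
#'   bin centers), one row per matrix row.
#' @return A `bin_table` object.
#' @export
bin_table <- function(counts, bin_centers) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(counts) == nrow(bin_centers),
            all(c("barcode", "x", "y") %in% names(bin_centers)))
  if (any(counts@x < 0)) abort("bin counts must be non-negative")
  if (anyDuplicated(colnames(counts))) abort("gene names must be unique")
  rownames(counts) <- bin_centers$barcode
  structure(list(counts = counts, bin_centers = as_tibble(bin_centers)),
            class = "bin_table")
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> %d bins x %d genes, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

# place non-overlapping circles (centers + radii) by rejection sampling
place_nuclei <- function(n, radii, rows, cols, max_tries_per_cell = 400L) {
  margin <- max(radii) + 3
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L
  tries <- 0L
  budget <- max_tries_per_cell * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > budget)
      abort(sprintf("could not place %d non-overlapping nuclei in a %d x %d image",
                    n, rows, cols))
    x <- runif(1, margin, cols - 1 - margin)
    y <- runif(1, margin, rows - 1 - margin)
    if (placed > 0L) {
      d2 <- (cx[1:placed] - x)^2 + (cy[1:placed] - y)^2
      if (any(d2 < (radii[1:placed] + radii[placed + 1L] + 2)^2)) next
    }
    placed <- placed + 1L
    cx[placed] <- x; cy[placed] <- y
  }
  list(cx = cx, cy = cy)
}

ellipse_vertices <- function(cx, cy, a, b, theta, n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta)
  y <- cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  cbind(x = x, y = y)
}

#' Simulate a synthetic H&E slide with matched binned counts
#'
#' Draws non-overlapping elliptical nuclei, assigns each cell a latent
#' program, renders an H&E-like image, and samples zero-inflated Poisson
#' counts that are scattered uniformly over the 2-um bins whose centers fall
#' inside each nucleus polygon. The bin grid is registered to image pixels:
#' at 0.5 um/px a 2-um bin is 4 px, and bin `(i, j)` has center
#' `((i + 0.5) * 4, (j + 0.5) * 4)`.
#'
#' Expected expression of cell `c` for gene `g` is the cell's program
#' profile entry times `exp(morphology_effect * (z_c . r_g))`, where `z_c`
#' are the standardized nucleus features (area, stain, local density) and
#' `r_g` are per-gene response loadings with a net-positive area component;
#' the expressed state of each (cell, gene) is Bernoulli(1 - zero_rate) and
#' expressed counts are Poisson(count_mean * expected). Everything is
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_slide` list: `image` ([slide_image()]), `polygons`
#'   ([nucleus_polygons()]), `bins` ([bin_table()]), and `truth` with
#'   `cells` (per-cell program, features, sampled totals), `expression`
#'   (cells x genes expected expression) and `counts` (cells x genes sampled
#'   counts, the conservation bookkeeping).
#' @export
simulate_slide <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, simulate_slide_impl(cfg))
}

simulate_slide_impl <- function(cfg) {
  rows <- cfg$image_size_px[1]; cols <- cfg$image_size_px[2]
  n <- cfg$n_cells; g <- cfg$n_genes; np <- cfg$n_programs

  genes <- sprintf("gene_%04d", seq_len(g))
  mito <- c("mt-Nd1", "mt-Co1", "mt-Cytb")
  genes[seq_len(min(3, g))] <- mito[seq_len(min(3, g))]

  program <- sample.int(np, n, replace = TRUE)
  radius_base <- seq(5.5, 9, length.out = np)
  stain_base <- seq(0.5, 0.82, length.out = np)

  radii <- radius_base[program] * runif(n, 0.9, 1.1)
  pos <- place_nuclei(n, radii, rows, cols)

  ecc <- runif(n, 0, 0.25)
  a <- radii * (1 + ecc)
  b <- pmax(4, radii * (1 - ecc))
  theta <- runif(n, 0, pi)
  verts <- purrr::pmap(list(pos$cx, pos$cy, a, b, theta), ellipse_vertices)
  polygons <- nucleus_polygons(verts)
  stain <- pmin(0.9, pmax(0.35, stain_base[program] + rnorm(n, 0, 0.04)))

  # observable nucleus features
  area_px <- polygons$area_px
  dmat <- as.matrix(stats::dist(cbind(pos$cx, pos$cy)))
  local_density <- rowSums(dmat < 64) - 1

  zf <- cbind(scale_safe(area_px), scale_safe(stain), scale_safe(local_density))

  # program profiles: per-program marker block, 8-fold over baseline 1
  profile <- matrix(1, np, g)
  non_mito <- setdiff(seq_len(g), seq_len(min(3, g)))
  blocks <- split(non_mito, sort(rep_len(seq_len(np), length(non_mito))))
  for (p in seq_len(np)) profile[p, blocks[[p]]] <- 8
  gene_scale <- exp(rnorm(g, 0, 0.3))
  gene_scale[seq_len(min(3, g))] <- 0.15      # mito genes stay a small count fraction

  # per-gene response loadings on (area, stain, density): area and stain have
  # positive mean loadings (larger, darker nuclei carry more transcripts),
  # so total true expression rises with nucleus area on average
  response <- cbind(rnorm(g, 0.6, 0.4), rnorm(g, 0.3, 0.4), rnorm(g, 0, 0.4))
  log_mod <- cfg$morphology_effect * (zf %*% t(response))

  expression <- profile[program, , drop = FALSE] *
    rep(gene_scale, each = n) * exp(log_mod)
  dimnames(expression) <- list(polygons$cell_id, genes)

  expressed <- matrix(rbinom(n * g, 1L, 1 - cfg$zero_rate), n, g)
  counts <- matrix(rpois(n * g, cfg$count_mean * expression), n, g) * expressed
  dimnames(counts) <- dimnames(expression)

  image <- render_he_image(rows, cols, polygons, stain, cfg$um_per_px)

  bins <- scatter_counts_to_bins(counts, polygons, rows, cols, genes)

  cells <- tibble(
    cell_id = polygons$cell_id, program = program, area_px = area_px,
    mean_stain = stain, local_density = local_density,
    total_umi = rowSums(counts)
  )
  structure(list(image = image, polygons = polygons, bins = bins,
                 truth = list(cells = cells, expression = expression,
                              counts = counts),
                 config = cfg),
            class = "synth_slide")
}

scale_safe <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

render_he_image <- function(rows, cols, polygons, stain, um_per_px) {
  eosin <- c(234, 203, 216)
  hema <- c(74, 48, 140)
  px <- array(0, dim = c(rows, cols, 3))
  for (ch in 1:3)
    px[, , ch] <- pmin(pmax(eosin[ch] + rnorm(rows * cols, 0, 4), 0), 255)
  for (k in seq_len(nrow(polygons))) {
    v <- polygons$vertices[[k]]
    c0 <- max(0L, floor(min(v[, 1]))); c1 <- min(cols - 1L, ceiling(max(v[, 1])))
    r0 <- max(0L, floor(min(v[, 2]))); r1 <- min(rows - 1L, ceiling(max(v[, 2])))
    sub <- rasterize_polygon(v, r1 - r0 + 1L, c1 - c0 + 1L, offset_x = c0, offset_y = r0)
    w <- which(sub, arr.ind = TRUE)
    if (nrow(w) == 0) next
    st <- stain[k]
    for (ch in 1:3) {
      val <- (1 - st) * eosin[ch] + st * hema[ch] +
        rnorm(nrow(w), 0, 3)
      px[cbind(w[, 1] + r0, w[, 2] + c0, ch)] <- pmin(pmax(val, 0), 255)
    }
  }
  slide_image(round_half_up(px), um_per_px, "synthetic")
}

# scatter each cell's sampled gene counts uniformly over the 2-um bins whose
# centers fall inside its polygon; returns the full-grid bin_table
scatter_counts_to_bins <- function(counts, polygons, rows, cols, genes) {
  bin_px <- 4L                                   # 2 um at 0.5 um/px
  nbr <- rows %/% bin_px; nbc <- cols %/% bin_px
  centers_x <- (seq_len(nbc) - 0.5) * bin_px     # i over columns
  centers_y <- (seq_len(nbr) - 0.5) * bin_px     # j over rows
  # row-major barcode layout: bin index = (j - 1) * nbc + i
  barcodes <- sprintf("bin_%04d_%04d",
                      rep(seq_len(nbr) - 1L, each = nbc),
                      rep(seq_len(nbc) - 1L, times = nbr))
  bc_x <- rep(centers_x, times = nbr)
  bc_y <- rep(centers_y, each = nbc)

  ti <- integer(0); tj <- integer(0); tx <- integer(0)
  for (k in seq_len(nrow(polygons))) {
    v <- polygons$vertices[[k]]
    i_rng <- which(centers_x >= min(v[, 1]) - 1 & centers_x <= max(v[, 1]) + 1)
    j_rng <- which(centers_y >= min(v[, 2]) - 1 & centers_y <= max(v[, 2]) + 1)
    cand <- expand.grid(i = i_rng, j = j_rng)
    inside <- point_in_polygon(centers_x[cand$i], centers_y[cand$j], v[, 1], v[, 2])
    cand <- cand[inside, , drop = FALSE]
    if (nrow(cand) == 0)
      abort(sprintf("nucleus %d contains no bin centers", k))
    bin_idx <- (cand$j - 1L) * nbc + cand$i
    y <- counts[k, ]
    for (gidx in which(y > 0)) {
      alloc <- as.integer(rmultinom(1, y[gidx], rep(1, nrow(cand))))
      nz <- which(alloc > 0)
      ti <- c(ti, bin_idx[nz]); tj <- c(tj, rep(gidx, length(nz)))
      tx <- c(tx, alloc[nz])
    }
  }
  m <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(nbr * nbc, length(genes)),
                            dimnames = list(barcodes, genes))
  bin_table(m, tibble(barcode = barcodes, x = bc_x, y = bc_y))
}

#' @export
print.synth_slide <- function(x, ...) {
  cat(sprintf("<synth_slide> %d cells, %d genes, image %d x %d px, seed %d\n",
              nrow(x$polygons), ncol(x$truth$counts),
              dim(x$image)[1], dim(x$image)[2], x$config$seed))
  invisible(x)
}
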