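# Shared fixtures and independent oracles. Slides are generated in code and
# cached per test run; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached_slide <- function(key, cfg) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_slide(cfg)
  .fixture_cache[[key]]
}

small_slide <- function() {
  cached_slide("small", synth_config(image_size_px = c(512L, 512L),
                                     n_cells = 30L, n_genes = 30L,
                                     n_programs = 2L, seed = 42L))
}

medium_slide <- function() {
  cached_slide("medium", synth_config(image_size_px = c(768L, 768L),
                                      n_cells = 80L, n_genes = 50L,
                                      n_programs = 3L, seed = 7L))
}

# independent O(bins x cells) point-in-polygon scan (first polygon wins):
# every bin is tested against every polygon, no spatial indexing
brute_force_assignment <- function(bins, polygons) {
  inside <- vapply(seq_len(nrow(polygons)), function(k) {
    v <- polygons$vertices[[k]]
    point_in_polygon(bins$bin_centers$x, bins$bin_centers$y, v[, 1], v[, 2])
  }, logical(nrow(bins$counts)))
  apply(inside, 1, function(row) {
    hit <- which(row)
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
}

# brute-force double loop over the 256 patch blocks
brute_force_patch_indices <- function(mask) {
  hits <- integer(0)
  for (r in 0:15) for (c in 0:15) {
    block <- mask[(16 * r + 1):(16 * r + 16), (16 * c + 1):(16 * c + 16)]
    if (any(block)) hits <- c(hits, 16L * r + c)
  }
  if (length(hits) == 0) 136L else sort(hits)
}

# exhaustive two-sided rank-sum p by enumerating all group assignments
exact_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  stats <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# layer-shape enumeration of the trainable parameter count
enumerate_parameters <- function(input_dim, hidden, d_genes, batch_norm = TRUE) {
  widths <- c(input_dim, hidden)
  total <- 0
  for (l in seq_along(hidden)) {
    total <- total + widths[l] * widths[l + 1] + widths[l + 1]
    if (batch_norm) total <- total + 2 * widths[l + 1]
  }
  total + hidden[length(hidden)] * d_genes + d_genes
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
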