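#' Construct a histology backbone adapter
#'
#' A backbone is anything that maps a 256 x 256 x 3 tile to a summary (CLS)
#' vector plus a 16 x 16 grid of patch tokens — the ViT-256/16 token layout.
#' The adapter declares its dimensions up front so downstream shape checks
#' are possible before any embedding runs.
#'
#' @param name Backbone name.
#' @param d_local Patch-token dimension (C1; default 192).
#' @param d_global CLS dimension (C2; default 384).
#' @param embed Function `(tile_array) -> list(cls, patch_tokens)` where
#'   `cls` has length `d_global` and `patch_tokens` is a 256 x `d_local`
#'   matrix ordered by patch index `k = 16 r + c`.
#' @return An `sc_backbone` object.
#' @export
backbone <- function(name, d_local, d_global, embed) {
  stopifnot(is.function(embed), d_local >= 1, d_global >= 1)
  structure(list(name = name, d_local = as.integer(d_local),
                 d_global = as.integer(d_global), embed = embed),
            class = "sc_backbone")
}

# per-patch and whole-tile summary statistics of a [0,1] tile array
patch_statistics <- function(arr) {
  a5 <- array(arr, dim = c(16, 16, 16, 16, 3))         # (in-r, r-blk, in-c, c-blk, ch)
  mean_s <- apply(a5, c(2, 4, 5), mean)
  sd_s <- sqrt(pmax(apply(a5, c(2, 4, 5), function(x) var(c(x))), 0))
  dx <- abs(a5[-1, , , , , drop = FALSE] - a5[-16, , , , , drop = FALSE])
  dy <- abs(a5[, , -1, , , drop = FALSE] - a5[, , -16, , , drop = FALSE])
  grad_s <- (apply(dx, c(2, 4, 5), mean) + apply(dy, c(2, 4, 5), mean)) / 2
  # flatten 16 x 16 x 3 -> 256 x 3 in patch-index order k = 16 r + c
  flat <- function(s) matrix(aperm(s, c(2, 1, 3)), 256, 3)
  cbind(flat(mean_s), flat(sd_s), flat(grad_s))        # 256 x 9
}

tile_statistics <- function(arr) {
  lum <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  h <- graphics::hist(lum, breaks = seq(0, 1, by = 0.1), plot = FALSE)$counts
  c(apply(arr, 3, mean), apply(arr, 3, sd),
    mean(abs(arr[-1, , ] - arr[-256, , ])), mean(abs(arr[, -1, ] - arr[, -256, ])),
    h / length(lum))                                    # 3 + 3 + 2 + 10 = 18 stats
}

#' Deterministic toy backbone for desk-scale runs and tests
#'
#' Computes interpretable per-patch statistics (channel means, standard
#' deviations and gradient energy) and whole-tile statistics (channel
#' moments, gradient energy, a 10-bin luminance histogram), then projects
#' them to the declared dimensions through fixed random matrices drawn once
#' from `seed`. Fully deterministic, no downloaded weights; it stands in for
#' a pre-trained vision transformer wherever the pipeline needs a backbone
#' at desk scale.
#'
#' @param d_local,d_global Output dimensions (defaults 192 / 384).
#' @param seed Seed for the fixed projection matrices (default 42).
#' @return An [backbone()] adapter.
#' @export
backbone_toy <- function(d_local = 192L, d_global = 384L, seed = 42L) {
  proj <- withr::with_seed(seed, list(
    patch = matrix(rnorm(9 * d_local), 9, d_local) / sqrt(9),
    tile = matrix(rnorm(18 * d_global), 18, d_global) / sqrt(18)
  ))
  backbone(
    name = sprintf("toy(seed=%d)", seed), d_local = d_local, d_global = d_global,
    embed = function(tile_array) {
      arr <- tile_array / 255
      list(cls = as.numeric(tile_statistics(arr) %*% proj$tile),
           patch_tokens = patch_statistics(arr) %*% proj$patch)
    })
}

#' Embed one tile through a backbone
#'
#' @param bb An [backbone()] adapter.
#' @param tile A `cell_tile` from [extract_cell_tile()] or a raw
#'   256 x 256 x 3 array.
#' @return A `backbone_output`: list with `cls` (length `d_global`) and
#'   `patch_tokens` (256 x `d_local`, patch-index order). Dimension
#'   mismatches against the adapter's declaration are an error.
#' @export
embed_tile <- function(bb, tile) {
  stopifnot(inherits(bb, "sc_backbone"))
  arr <- if (inherits(tile, "cell_tile")) tile$tile else tile
  if (!is.array(arr) || !identical(dim(arr), c(256L, 256L, 3L)))
    abort("tile must be a 256 x 256 x 3 array")
  out <- bb$embed(arr)
  if (length(out$cls) != bb$d_global)
    abort(sprintf("backbone '%s' declared d_global = %d but returned %d",
                  bb$name, bb$d_global, length(out$cls)))
  if (!identical(dim(out$patch_tokens), c(256L, as.integer(bb$d_local))))
    abort(sprintf("backbone '%s' declared d_local = %d but returned %s",
                  bb$name, bb$d_local, paste(dim(out$patch_tokens), collapse = " x ")))
  structure(list(cls = out$cls, patch_tokens = out$patch_tokens),
            class = "backbone_output")
}

#' Fuse local and global histology features for one cell
#'
#' The local feature C1 is the average of the patch tokens overlapped by the
#' nucleus; the global feature C2 is the CLS vector of the whole tile; the
#' fused feature is their concatenation `z = [C1 | C2]` (dimension 576 under
#' the default 192 + 384).
#'
#' @param out A [embed_tile()] result.
#' @param indices 0-based nucleus patch indices from
#'   [nucleus_patch_indices()]; must be non-empty, all in `[0, 255]`.
#' @return A `histology_feature`: list with `z`, `c1`, `c2`.
#' @export
fuse_features <- function(out, indices) {
  stopifnot(inherits(out, "backbone_output"))
  if (length(indices) == 0) abort("nucleus patch index set is empty")
  if (any(indices < 0 | indices > 255)) abort("patch indices must be in [0, 255]")
  c1 <- colMeans(out$patch_tokens[indices + 1L, , drop = FALSE])
  structure(list(z = c(c1, out$cls), c1 = c1, c2 = out$cls),
            class = "histology_feature")
}

#' Embed every cell on a slide into fused histology features
#'
#' Extracts the 256-px tile of each nucleus, embeds it, and fuses C1/C2.
#' The C1/C2 split is kept so the ablation harness can train on either part
#' alone.
#'
#' @param image A [slide_image()] at the 0.5 um/px working scale.
#' @param polygons A [nucleus_polygons()] tibble.
#' @param bb A [backbone()] adapter (default [backbone_toy()]).
#' @return A `histology_features` object: `z` (cells x (d_local + d_global)
#'   matrix), `d_local`, `d_global`, and a `cells` tibble (`cell_id`,
#'   tile origin, number of nucleus patches).
#' @export
embed_cells <- function(image, polygons, bb = backbone_toy()) {
  n <- nrow(polygons)
  z <- matrix(NA_real_, n, bb$d_local + bb$d_global,
              dimnames = list(polygons$cell_id, NULL))
  info <- vector("list", n)
  for (k in seq_len(n)) {
    tl <- extract_cell_tile(image, polygons[k, ])
    emb <- embed_tile(bb, tl)
    fz <- fuse_features(emb, tl$nucleus_patch_indices)
    z[k, ] <- fz$z
    info[[k]] <- tibble(cell_id = tl$cell_id, x0 = tl$origin[["x0"]],
                        y0 = tl$origin[["y0"]],
                        n_patches = length(tl$nucleus_patch_indices))
  }
  structure(list(z = z, d_local = bb$d_local, d_global = bb$d_global,
                 backbone = bb$name, cells = dplyr::bind_rows(info)),
            class = "histology_features")
}

#' @export
print.histology_features <- function(x, ...) {
  cat(sprintf("<histology_features> %d cells, dim %d = %d (local) + %d (global), backbone %s\n",
              nrow(x$z), ncol(x$z), x$d_local, x$d_global, x$backbone))
  invisible(x)
}

#' Slice a feature matrix to one ablation variant
#'
#' @param features A [embed_cells()] result.
#' @param variant `"full"` (z), `"local_only"` (C1 columns) or
#'   `"global_only"` (C2 columns).
#' @return The matching cells x dim matrix.
#' @export
feature_slice <- function(features, variant = c("full", "local_only", "global_only")) {
  variant <- match.arg(variant)
  switch(variant,
         full = features$z,
         local_only = features$z[, seq_len(features$d_local), drop = FALSE],
         global_only = features$z[, features$d_local + seq_len(features$d_global),
                                  drop = FALSE])
}
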