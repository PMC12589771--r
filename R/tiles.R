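#' Rasterize a polygon into a boolean mask
#'
#' A mask pixel is true iff its center (integer coordinates in the tile
#' frame) lies inside the polygon, boundary included.
#'
#' @param vertices n x 2 matrix of `(x, y)` polygon vertices.
#' @param nrow,ncol Mask dimensions.
#' @param offset_x,offset_y Frame origin: mask pixel `(r, c)` (0-based) has
#'   slide coordinates `(x = offset_x + c, y = offset_y + r)`.
#' @return Logical `nrow x ncol` matrix.
#' @keywords internal
rasterize_polygon <- function(vertices, nrow, ncol, offset_x = 0, offset_y = 0) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  # restrict the scan to the polygon's bounding box
  c0 <- max(0L, floor(min(vx) - offset_x)); c1 <- min(ncol - 1L, ceiling(max(vx) - offset_x))
  r0 <- max(0L, floor(min(vy) - offset_y)); r1 <- min(nrow - 1L, ceiling(max(vy) - offset_y))
  mask <- matrix(FALSE, nrow, ncol)
  if (c1 < c0 || r1 < r0) return(mask)
  cc <- c0:c1; rr <- r0:r1
  grid <- expand.grid(r = rr, c = cc)
  inside <- point_in_polygon(grid$c + offset_x, grid$r + offset_y, vx, vy)
  mask[cbind(grid$r + 1L, grid$c + 1L)] <- inside
  mask
}

#' Patch indices overlapped by a nucleus mask
#'
#' A 256 x 256 tile splits into a 16 x 16 grid of 16-px patches. Patch `k`
#' (0-based, `k = 16 * r + c`) covers the half-open pixel block
#' `[16r, 16r + 16) x [16c, 16c + 16)`. A patch qualifies when at least one
#' mask pixel in its block is true. When no patch qualifies (the defensive
#' empty-mask case) the single central patch (index 136, containing pixel
#' (128, 128)) is returned so the local feature is always defined.
#'
#' @param mask Logical 256 x 256 matrix (rows x cols).
#' @return Sorted integer vector of 0-based patch indices in `[0, 255]`.
#' @export
nucleus_patch_indices <- function(mask) {
  if (!is.matrix(mask) || !identical(dim(mask), c(256L, 256L)))
    abort("`mask` must be a 256 x 256 logical matrix.")
  hit <- matrix(FALSE, 16, 16)
  for (r in 0:15) for (c in 0:15) {
    if (any(mask[(16 * r + 1):(16 * r + 16), (16 * c + 1):(16 * c + 16)]))
      hit[r + 1, c + 1] <- TRUE
  }
  k <- which(t(hit)) - 1L              # column-major over t(hit) => k = 16 r + c, ascending
  if (length(k) == 0) k <- 136L
  as.integer(k)
}

#' Extract the 256-px tile and nucleus mask for one cell
#'
#' The tile is centered on the nucleus centroid (origin =
#' `round_half_up(centroid) - tile_px / 2` per axis); regions falling outside
#' the slide are padded with white (255, 255, 255), the H&E background color.
#' The mask rasterizes the polygon into the tile frame; the overlapped patch
#' indices are attached via [nucleus_patch_indices()].
#'
#' @param image A [slide_image()] at the working scale (0.5 um/px).
#' @param polygon One row of a [nucleus_polygons()] tibble.
#' @param tile_px Tile side in pixels (default 256).
#' @return A `cell_tile`: list with `cell_id`, `tile` (tile_px^3 array),
#'   `mask`, `origin` (`c(x0, y0)`), `nucleus_patch_indices`.
#' @export
extract_cell_tile <- function(image, polygon, tile_px = 256L) {
  stopifnot(inherits(image, "slide_image"), tile_px >= 16)
  d <- dim(image$pixels)
  cx <- polygon$centroid_x[[1]]; cy <- polygon$centroid_y[[1]]
  if (cx < 0 || cy < 0 || cx > d[2] - 1 || cy > d[1] - 1)
    abort(sprintf("centroid (%.1f, %.1f) outside image bounds", cx, cy))
  x0 <- round_half_up(cx) - tile_px / 2
  y0 <- round_half_up(cy) - tile_px / 2
  tile <- array(255L, dim = c(tile_px, tile_px, 3L))
  # in-bounds overlap between tile frame and slide
  rr <- max(0, y0):min(d[1] - 1, y0 + tile_px - 1)
  cc <- max(0, x0):min(d[2] - 1, x0 + tile_px - 1)
  if (length(rr) > 0 && length(cc) > 0 && rr[1] <= rr[length(rr)])
    tile[rr - y0 + 1, cc - x0 + 1, ] <- image$pixels[rr + 1, cc + 1, ]
  mask <- rasterize_polygon(polygon$vertices[[1]], tile_px, tile_px,
                            offset_x = x0, offset_y = y0)
  idx <- if (tile_px == 256L) nucleus_patch_indices(mask) else integer(0)
  structure(list(cell_id = polygon$cell_id[[1]], tile = tile, mask = mask,
                 origin = c(x0 = x0, y0 = y0), nucleus_patch_indices = idx),
            class = "cell_tile")
}
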