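#' Round half away from zero
#'
#' Deterministic rounding used for all pixel-grid arithmetic: halves round up,
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Test whether points lie inside a polygon
#'
#' Vectorized even-odd ray casting with an explicit on-boundary check: points
#' on a polygon edge or vertex count as inside. This boundary-inclusive rule is
#' the one used everywhere in the package (bin-to-nucleus assignment, mask
#' rasterization), so a 2-um bin whose center falls exactly on a nucleus
#' outline is attributed to that nucleus.
#'
#' @param px,py Numeric vectors of point coordinates (x = column, y = row).
#' @param vx,vy Numeric vectors of polygon vertex coordinates, in order,
#'   without a repeated closing vertex.
#' @param tol Absolute tolerance for the on-edge test.
#' @return Logical vector, one entry per point.
#' @examples
#' point_in_polygon(c(0.5, 2), c(0.5, 2), c(0, 1, 1, 0), c(0, 0, 1, 1))
#' @export
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  stopifnot(length(px) == length(py), length(vx) == length(vy), length(vx) >= 3)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    scale <- abs(xj - xi) + abs(yj - yi) + 1
    on_edge <- on_edge | (abs(cross) <= tol * scale & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Polygon area by the shoelace formula
#'
#' @param vx,vy Vertex coordinates in order (no repeated closing vertex).
#' @return Area in squared coordinate units.
#' @export
polygon_area <- function(vx, vy) {
  stopifnot(length(vx) == length(vy), length(vx) >= 3)
  j <- c(seq_along(vx)[-1], 1L)
  abs(sum(vx * vy[j] - vx[j] * vy)) / 2
}

#' Polygon centroid (area-weighted)
#' @inheritParams polygon_area
#' @return Numeric `c(x, y)`.
#' @keywords internal
polygon_centroid <- function(vx, vy) {
  j <- c(seq_along(vx)[-1], 1L)
  cr <- vx * vy[j] - vx[j] * vy
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(vx), mean(vy)))
  c(sum((vx + vx[j]) * cr) / (6 * a), sum((vy + vy[j]) * cr) / (6 * a))
}

# stable content hash for config/artifact provenance
config_hash <- function(x) rlang::hash(x)

sigmoid <- function(x) 1 / (1 + exp(-x))
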