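#' Build a nucleus polygon table
#'
#' Nucleus polygons are kept as a tibble with one row per nucleus: `cell_id`,
#' a `vertices` list-column (each element an n x 2 matrix of `(x, y)` pixel
#' coordinates, 0-based, x = column), the area-weighted centroid, and the
#' shoelace area in squared pixels. Polygons with fewer than 3 vertices or
#' zero area are dropped.
#'
#' @param vertex_lists List of n x 2 numeric matrices (or data frames with
#'   columns x, y), one per nucleus.
#' @param cell_ids Optional character ids; defaults to `cell_0001`, ...
#' @return A tibble of class `nucleus_polygons`.
#' @export
nucleus_polygons <- function(vertex_lists, cell_ids = NULL) {
  stopifnot(is.list(vertex_lists))
  vertex_lists <- purrr::map(vertex_lists, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    colnames(v) <- c("x", "y")
    v
  })
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell_%04d", seq_along(vertex_lists))
  stopifnot(length(cell_ids) == length(vertex_lists), !anyDuplicated(cell_ids))
  keep <- purrr::map_lgl(vertex_lists, function(v)
    nrow(v) >= 3 && polygon_area(v[, 1], v[, 2]) > 0)
  vertex_lists <- vertex_lists[keep]
  cell_ids <- cell_ids[keep]
  cent <- purrr::map(vertex_lists, ~ polygon_centroid(.x[, 1], .x[, 2]))
  out <- tibble(
    cell_id = as.character(cell_ids),
    vertices = vertex_lists,
    centroid_x = purrr::map_dbl(cent, 1),
    centroid_y = purrr::map_dbl(cent, 2),
    area_px = purrr::map_dbl(vertex_lists, ~ polygon_area(.x[, 1], .x[, 2]))
  )
  class(out) <- c("nucleus_polygons", class(out))
  out
}

#' Segment nuclei in a slide image via a pluggable engine
#'
#' The package does not bundle a segmentation network; instead any engine
#' satisfying a one-function contract can be plugged in: a list with elements
#' `name` and `run`, where `run(raster)` takes the `rows x cols x 3` pixel
#' array and returns a list of vertex matrices (`(x, y)` pixel coordinates).
#' Star-convex-polygon tools (StarDist-style) fit this contract directly.
#' Degenerate engine output (fewer than 3 vertices, zero area) is discarded.
#'
#' @param image A [slide_image()], typically [percentile_normalize()]d first.
#' @param engine A segmentation engine; see [engine_replay()] for the
#'   ground-truth replay engine used in tests and synthetic runs.
#' @return A [nucleus_polygons()] tibble (possibly empty).
#' @export
segment_nuclei <- function(image, engine) {
  stopifnot(inherits(image, "slide_image"))
  if (!is.list(engine) || !is.function(engine$run))
    abort("`engine` must be a list with a `run(raster)` function.")
  res <- tryCatch(engine$run(image$pixels), error = function(e)
    abort(sprintf("segmentation engine '%s' failed: %s",
                  engine$name %||% "?", conditionMessage(e))))
  if (length(res) == 0) return(nucleus_polygons(list()))
  ids <- names(res) %||% NULL
  if (!is.null(ids) && any(ids == "")) ids <- NULL
  nucleus_polygons(res, cell_ids = ids)
}

#' Ground-truth replay segmentation engine
#'
#' Wraps an existing polygon table as a segmentation engine, so pipelines can
#' run segmentation-free on synthetic slides (whose true polygons are known)
#' or on externally supplied GeoJSON.
#'
#' @param polygons A [nucleus_polygons()] tibble.
#' @return An engine usable with [segment_nuclei()].
#' @export
engine_replay <- function(polygons) {
  stopifnot(inherits(polygons, "nucleus_polygons"))
  list(name = "replay",
       run = function(raster) setNames(polygons$vertices, polygons$cell_id))
}
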