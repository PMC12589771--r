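#' Read and write slide images as TIFF
#'
#' @param image A [slide_image()].
#' @param path Output path (`.tiff`).
#' @return `write_slide_tiff` returns `path` invisibly; `read_slide_tiff`
#'   returns a [slide_image()].
#' @export
write_slide_tiff <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  tiff::writeTIFF(array(image$pixels / 255, dim(image$pixels)), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_slide_tiff
#' @param um_per_px Physical scale to attach on read.
#' @param name Slide name to attach on read.
#' @export
read_slide_tiff <- function(path, um_per_px, name = "slide") {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  slide_image(round_half_up(px[, , 1:3, drop = FALSE] * 255), um_per_px, name)
}

#' Read and write nucleus polygons as GeoJSON
#'
#' Polygons are stored as a GeoJSON `FeatureCollection` of `Polygon`
#' features in pixel coordinates (x = column, y = row, 0-based), with the
#' nucleus id under the `cell_id` property. Full double precision is kept so
#' vertices round-trip within 1e-9.
#'
#' @param polygons A [nucleus_polygons()] tibble.
#' @param path Output path (`.geojson`).
#' @export
write_polygons_geojson <- function(polygons, path) {
  stopifnot(inherits(polygons, "nucleus_polygons"))
  features <- purrr::map2(polygons$vertices, polygons$cell_id, function(v, id) {
    ring <- rbind(v, v[1, , drop = FALSE])          # closed ring
    list(type = "Feature",
         properties = list(cell_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring)[, 1]) |>
                                              purrr::map(unname)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  verts <- purrr::map(js$features, function(f) {
    ring <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]],
                                      ~ as.numeric(unlist(.x))))
    ring[-nrow(ring), , drop = FALSE]               # drop closing vertex
  })
  ids <- purrr::map_chr(js$features, ~ .x$properties$cell_id)
  nucleus_polygons(verts, cell_ids = ids)
}

#' Read and write a bin table as MTX triplet plus parquet positions
#'
#' Counts go to `matrix.mtx` with `barcodes.tsv` / `features.tsv` sidecars
#' (the MTX-triplet layout of feature-barcode matrices); bin center pixel
#' coordinates go to `positions.parquet` with columns `barcode`, `x`, `y`.
#'
#' @param bins A [bin_table()].
#' @param dir Directory to write into (created if needed).
#' @export
write_bin_table <- function(bins, dir) {
  stopifnot(inherits(bins, "bin_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(bins$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(bins$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(bins$counts), file.path(dir, "features.tsv"))
  arrow::write_parquet(bins$bin_centers, file.path(dir, "positions.parquet"))
  invisible(dir)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(m) <- readLines(file.path(dir, "features.tsv"))
  pos <- as_tibble(as.data.frame(arrow::read_parquet(file.path(dir, "positions.parquet"))))
  bin_table(m, pos[match(rownames(m), pos$barcode), ])
}

#' Write a synthetic slide to disk as a pipeline fixture
#'
#' Writes the image as TIFF, polygons as GeoJSON, bin counts as an MTX
#' triplet with a parquet positions table, ground truth as h5ad, and a
#' `metadata.json` with the generator configuration, its hash and seed.
#' Everything round-trips losslessly through [read_fixture()].
#'
#' @param slide A [simulate_slide()] result.
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(slide, dir) {
  stopifnot(inherits(slide, "synth_slide"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) abort(sprintf("directory '%s' not writable", dir))
  paths <- c(
    image = file.path(dir, "image.tiff"),
    polygons = file.path(dir, "polygons.geojson"),
    counts = file.path(dir, "counts"),
    truth = file.path(dir, "truth.h5ad"),
    metadata = file.path(dir, "metadata.json")
  )
  write_slide_tiff(slide$image, paths[["image"]])
  write_polygons_geojson(slide$polygons, paths[["polygons"]])
  write_bin_table(slide$bins, paths[["counts"]])
  tr <- slide$truth
  write_h5ad(paths[["truth"]],
             X = Matrix::Matrix(tr$counts, sparse = TRUE),
             obs = as.data.frame(tr$cells[-1], row.names = tr$cells$cell_id),
             var = data.frame(row.names = colnames(tr$counts)),
             layers = list(expected = tr$expression),
             uns = list(seed = slide$config$seed,
                        config_hash = config_hash(unclass(slide$config))))
  jsonlite::write_json(
    c(unclass(slide$config), list(config_hash = config_hash(unclass(slide$config)))),
    paths[["metadata"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  truth <- read_h5ad(file.path(dir, "truth.h5ad"))
  list(
    image = read_slide_tiff(file.path(dir, "image.tiff"), meta$um_per_px, "synthetic"),
    polygons = read_polygons_geojson(file.path(dir, "polygons.geojson")),
    bins = read_bin_table(file.path(dir, "counts")),
    truth = truth,
    metadata = meta
  )
}
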