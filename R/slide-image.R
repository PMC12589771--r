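#' Construct a slide image
#'
#' A slide image is an RGB pixel raster with a physical scale. Pixels are
#' stored as an integer array `rows x cols x 3` with values in 0..255.
#' Coordinates throughout the package are 0-based, `x` = column and
#' `y` = row, with pixel centers at integer coordinates.
#'
#' @param pixels Numeric/integer array of dimension `c(rows, cols, 3)`,
#'   values in `[0, 255]`.
#' @param um_per_px Physical pixel size in microns per pixel (> 0).
#' @param name Optional slide name.
#' @return A `slide_image` object.
#' @export
slide_image <- function(pixels, um_per_px, name = "slide") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 1, dim(pixels)[2] >= 1)
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 || um_per_px <= 0)
    abort("`um_per_px` must be a single positive number.")
  if (min(pixels) < 0 || max(pixels) > 255)
    abort("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, um_per_px = um_per_px, name = name),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image '%s'> %d x %d px, %.4g um/px (%.0f x %.0f um)\n",
              x$name, d[1], d[2], x$um_per_px,
              d[1] * x$um_per_px, d[2] * x$um_per_px))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

#' Rescale a slide image to a target physical resolution
#'
#' Histology inputs arrive at arbitrary scanner resolutions; all downstream
#' geometry (256-px tiles, 16-px patches) assumes 0.5 um/px, at which a
#' 16 x 16-px patch covers 8 x 8 um — roughly one cell. Resampling is
#' bilinear; output dimensions are `round(dim * um_per_px / target)`.
#'
#' @param image A [slide_image()].
#' @param target_um_per_px Target scale, microns per pixel (default 0.5).
#' @return A `slide_image` at the target scale. If the image is already at
#'   the target scale it is returned unchanged.
#' @seealso [rescale_polygons()] to bring segmentation output (drawn at the
#'   source scale) into the same frame.
#' @export
rescale_to_target <- function(image, target_um_per_px = 0.5) {
  stopifnot(inherits(image, "slide_image"))
  if (!is.numeric(target_um_per_px) || target_um_per_px <= 0)
    abort("`target_um_per_px` must be positive.")
  f <- image$um_per_px / target_um_per_px
  if (abs(f - 1) < 1e-12) return(image)
  d <- dim(image$pixels)
  new_r <- max(1L, as.integer(round_half_up(d[1] * f)))
  new_c <- max(1L, as.integer(round_half_up(d[2] * f)))
  out <- EBImage::resize(array(image$pixels / 255, d), w = new_r, h = new_c,
                         filter = "bilinear")
  out <- pmin(pmax(out, 0), 1)
  slide_image(round_half_up(out * 255), target_um_per_px, image$name)
}

#' Rescale nucleus polygons by a linear factor
#'
#' Companion to [rescale_to_target()]: polygons segmented at the source image
#' scale are multiplied by `factor = um_per_px_source / um_per_px_target` so
#' they stay registered with the rescaled raster.
#'
#' @param polygons A nucleus polygon tibble (see [nucleus_polygons()]).
#' @param factor Positive linear scale factor applied to all coordinates.
#' @return The rescaled polygon tibble (areas scale by `factor^2`).
#' @export
rescale_polygons <- function(polygons, factor) {
  stopifnot(is.numeric(factor), factor > 0)
  polygons$vertices <- purrr::map(polygons$vertices, ~ .x * factor)
  polygons$centroid_x <- polygons$centroid_x * factor
  polygons$centroid_y <- polygons$centroid_y * factor
  polygons$area_px <- polygons$area_px * factor^2
  polygons
}

#' Percentile-normalize a slide image
#'
#' Per-channel linear contrast stretch mapping the `p_low` percentile to 0 and
#' the `p_high` percentile to 255, clipped to `[0, 255]` — the standard
#' pre-segmentation normalization for nuclear-segmentation engines. Channels
#' with no intensity spread are returned unchanged with a warning.
#'
#' @param image A [slide_image()].
#' @param p_low,p_high Percentiles in `[0, 100]`, `p_low < p_high`.
#' @return A normalized `slide_image`.
#' @export
percentile_normalize <- function(image, p_low = 1.0, p_high = 99.8) {
  stopifnot(inherits(image, "slide_image"))
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    abort("need 0 <= p_low < p_high <= 100")
  px <- image$pixels
  flat <- integer(0)
  for (ch in 1:3) {
    v <- px[, , ch]
    q <- quantile(v, c(p_low, p_high) / 100, names = FALSE)
    if (q[2] - q[1] < .Machine$double.eps) {
      flat <- c(flat, ch)
      next
    }
    px[, , ch] <- pmin(pmax(round_half_up((v - q[1]) / (q[2] - q[1]) * 255), 0), 255)
  }
  if (length(flat))
    warn(sprintf("channel(s) %s have no intensity spread; left unchanged",
                 paste(flat, collapse = ", ")))
  slide_image(px, image$um_per_px, image$name)
}

#' Plot a slide image
#'
#' @param object A [slide_image()].
#' @param max_px Downsample so the longer side is at most this many pixels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slide_image <- function(object, max_px = 512, ...) {
  px <- object$pixels
  d <- dim(px)
  step <- max(1L, ceiling(max(d[1:2]) / max_px))
  rows <- seq(1L, d[1], by = step); cols <- seq(1L, d[2], by = step)
  df <- expand.grid(y = rows - 1L, x = cols - 1L)
  df$fill <- grDevices::rgb(px[rows, cols, 1][cbind(match(df$y + 1L, rows), match(df$x + 1L, cols))],
                            px[rows, cols, 2][cbind(match(df$y + 1L, rows), match(df$x + 1L, cols))],
                            px[rows, cols, 3][cbind(match(df$y + 1L, rows), match(df$x + 1L, cols))],
                            maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$name,
                  subtitle = sprintf("%.3g um/px", object$um_per_px),
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
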