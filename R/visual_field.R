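#' Calibrated visual-field raster
#'
#' A `vf_grid` maps a square pixel raster onto degrees of visual angle.
#' Pixel centres are symmetric about fixation, which sits at `(0, 0)`;
#' x increases rightward with column index, y increases upward (so row 1
#' is the top of the raster).  Images on a grid are vectorized in
#' row-major order.
#'
#' @param n_rows,n_cols Raster size in pixels.
#' @param extent Full width of the raster in degrees of visual angle.
#' @return A `vf_grid` object.
#' @examples
#' g <- vf_grid()
#' g$deg_per_px
#' @export
vf_grid <- function(n_rows = 150, n_cols = 150, extent = 10) {
  stopifnot(n_rows >= 2, n_cols >= 2, extent > 0)
  structure(
    list(
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      extent = extent,
      deg_per_px = extent / n_cols
    ),
    class = "vf_grid"
  )
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf(
    "<vf_grid> %d x %d px, %.3g deg wide (%.4g deg/px)\n",
    x$n_rows, x$n_cols, x$extent, x$deg_per_px
  ))
  invisible(x)
}

grid_axes <- function(grid) {
  dpp <- grid$deg_per_px
  list(
    x = (seq_len(grid$n_cols) - (grid$n_cols + 1) / 2) * dpp,
    y = ((grid$n_rows + 1) / 2 - seq_len(grid$n_rows)) * dpp
  )
}

#' Pixel-centre coordinates of a grid
#'
#' Returns one row per pixel in row-major (vectorization) order.
#'
#' @param grid A [vf_grid()].
#' @return A tibble with columns `x` and `y` in degrees.
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "vf_grid"))
  ax <- grid_axes(grid)
  tibble::tibble(
    x = rep(ax$x, times = grid$n_rows),
    y = rep(ax$y, each = grid$n_cols)
  )
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

check_same_grid <- function(a, b, what = "objects") {
  if (!grids_equal(a, b)) {
    stop(sprintf(
      "%s live on different grids: %dx%d px / %.4g deg vs %dx%d px / %.4g deg",
      what, a$n_rows, a$n_cols, a$extent, b$n_rows, b$n_cols, b$extent
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Vectorize an image raster
#'
#' Flattens a raster to a length `n_rows * n_cols` vector in row-major
#' order (all pixels of the first row, then the second row, ...).  The
#' inverse, [devectorize_image()], restores the raster exactly.
#'
#' @param img A numeric matrix (raster).
#' @return A numeric vector of length `nrow(img) * ncol(img)`.
#' @export
vectorize_image <- function(img) {
  stopifnot(is.matrix(img))
  as.vector(t(img))
}

#' @rdname vectorize_image
#' @param v A numeric vector of length `n_rows * n_cols`.
#' @param grid The [vf_grid()] the vector lives on.
#' @export
devectorize_image <- function(v, grid) {
  stopifnot(inherits(grid, "vf_grid"))
  if (length(v) != grid$n_rows * grid$n_cols) {
    stop(sprintf(
      "vector of length %d cannot be reshaped to a %d x %d raster",
      length(v), grid$n_rows, grid$n_cols
    ), call. = FALSE)
  }
  matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Write a raster as a PNG with a JSON sidecar
#'
#' Values are min-max scaled for display; grid calibration and any extra
#' metadata are stored alongside in `<path>.json`.
#'
#' @param img Raster matrix.
#' @param path Output PNG path.
#' @param grid Optional [vf_grid()] recorded in the sidecar.
#' @param meta Named list of additional metadata.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path, grid = NULL, meta = list()) {
  stopifnot(is.matrix(img))
  rng <- range(img, finite = TRUE)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  png::writePNG(scaled, target = path)
  side <- c(
    list(n_rows = nrow(img), n_cols = ncol(img), value_range = rng),
    if (!is.null(grid)) list(extent_deg = grid$extent, deg_per_px = grid$deg_per_px),
    meta
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
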