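#' Square simulation grid
#'
#' Defines the raster on which geometries are drawn and fields computed.
#' Pixel centers sit at `(i - 0.5) * pixel_size` with the origin at the
#' lower-left corner; the first matrix index runs along x, the second along y.
#'
#' @param n Pixels per side.
#' @param extent Physical side length in micrometers.
#' @return A `grid_spec` object with elements `n`, `extent` and
#'   `pixel_size` (= `extent / n`, micrometers per pixel).
#' @examples
#' grid_spec(500, 3)
#' @export
grid_spec <- function(n, extent) {
  stopifnot(length(n) == 1, length(extent) == 1)
  n <- as.integer(n)
  if (is.na(n) || n <= 0) stop("`n` must be a positive integer")
  if (!is.finite(extent) || extent <= 0) stop("`extent` must be positive")
  structure(list(n = n, extent = as.numeric(extent),
                 pixel_size = as.numeric(extent) / n),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, %.3g x %.3g um (%.4g um/px)\n",
              x$n, x$n, x$extent, x$extent, x$pixel_size))
  invisible(x)
}

# Pixel-center coordinates (um) along one axis.
grid_centers <- function(grid) (seq_len(grid$n) - 0.5) * grid$pixel_size

#' Central sampling mask
#'
#' Builds the circular region-of-interest mask used to sample field maps and
#' signals away from any geometry or transform edge effects. The default
#' covers half of the grid area.
#'
#' @param grid A [grid_spec()].
#' @param fraction Fraction of the grid area covered by the mask. The disk
#'   is exact up to `pi/4` (~0.785); `1` selects the whole grid.
#' @return A `sample_mask` object wrapping a logical matrix.
#' @export
sample_mask <- function(grid, fraction = 0.5) {
  stopifnot(inherits(grid, "grid_spec"), fraction > 0, fraction <= 1)
  if (fraction >= 1) {
    m <- matrix(TRUE, grid$n, grid$n)
  } else {
    xs <- grid_centers(grid)
    ctr <- grid$extent / 2
    r2 <- outer((xs - ctr)^2, (xs - ctr)^2, "+")
    rmax <- grid$extent * sqrt(fraction / pi)
    m <- r2 <= rmax^2
  }
  structure(list(grid = grid, mask = m, fraction = fraction),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf("<sample_mask> central disk, %.0f%% of %d x %d grid\n",
              100 * x$fraction, x$grid$n, x$grid$n))
  invisible(x)
}

# Shared check that two raster objects live on the same grid.
check_same_grid <- function(...) {
  gs <- list(...)
  n <- vapply(gs, function(g) g$n, integer(1))
  e <- vapply(gs, function(g) g$extent, numeric(1))
  if (length(unique(n)) != 1 || length(unique(signif(e, 10))) != 1)
    stop("inputs are defined on different grids")
  invisible(TRUE)
}
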