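#' Elliptical cross-section specification
#'
#' Eccentricity `e` and major/minor axis ratio `q` are related by
#' `e = sqrt(1 - 1/q^2)`. The reference cases are e = 0, 0.66, 0.80 and 0.87,
#' i.e. axis ratios 1, 4/3, 5/3 and 2.
#'
#' @param eccentricity Eccentricity in `[0, 1)`. Give either this or
#'   `axis_ratio`.
#' @param axis_ratio Major/minor axis ratio (>= 1).
#' @param rotation In-plane angle of the major axis relative to the
#'   transverse projection of the applied field, radians.
#' @return An `ellipse_spec` list with both parameterizations filled in.
#' @export
ellipse_spec <- function(eccentricity = NULL, axis_ratio = NULL,
                         rotation = 0) {
  if (is.null(eccentricity) && is.null(axis_ratio))
    stop("give `eccentricity` or `axis_ratio`")
  if (is.null(axis_ratio)) {
    stopifnot(eccentricity >= 0, eccentricity < 1)
    axis_ratio <- 1 / sqrt(1 - eccentricity^2)
  } else {
    stopifnot(axis_ratio >= 1)
    eccentricity <- sqrt(1 - 1 / axis_ratio^2)
  }
  structure(list(eccentricity = eccentricity, axis_ratio = axis_ratio,
                 rotation = rotation),
            class = "ellipse_spec")
}

#' Single nested-ellipse axon
#'
#' Builds one myelinated axon with elliptical cross-section, centered in the
#' grid. The semi-axes are `a = r_equiv * sqrt(q)`, `b = r_equiv / sqrt(q)`
#' so the total fiber area `pi * r_equiv^2` is identical across all
#' eccentricities; the inner boundary is the outer scaled by `g`, conserving
#' the intra-axonal area too. Differences between eccentricity cases are
#' therefore attributable to shape alone.
#'
#' @param spec An [ellipse_spec()].
#' @param g Target g-ratio.
#' @param grid A [grid_spec()] (the reference grid is 500 px over 3 um).
#' @param r_equiv Area-equivalent outer radius, um.
#' @return An [axon_set()] with one polygonal axon (non-periodic).
#' @examples
#' ax <- make_single_ellipse_axon(ellipse_spec(0.87), g = 0.7,
#'                                grid = grid_spec(500, 3))
#' @export
make_single_ellipse_axon <- function(spec, g = 0.7, grid,
                                     r_equiv = 0.5) {
  stopifnot(inherits(spec, "ellipse_spec"), inherits(grid, "grid_spec"),
            g > 0, g < 1, r_equiv > 0)
  q <- spec$axis_ratio
  a <- r_equiv * sqrt(q); b <- r_equiv / sqrt(q)
  if (2 * a > 0.8 * grid$extent)
    stop(sprintf(paste0("ellipse (major axis %.3g um) exceeds the grid: ",
                        "an extent of at least %.3g um is required"),
                 2 * a, 2 * a / 0.8))
  ctr <- grid$extent / 2
  if (spec$eccentricity == 0) {
    # exact circle: rotation-invariant by construction
    ax <- tibble::tibble(id = 1L, x = ctr, y = ctr,
                         r_outer = r_equiv, r_inner = g * r_equiv,
                         outer = list(NULL), inner = list(NULL),
                         kind = "circle")
  } else {
    outer <- ellipse_polygon(ctr, ctr, a, b, spec$rotation)
    inner <- ellipse_polygon(ctr, ctr, g * a, g * b, spec$rotation)
    ax <- tibble::tibble(id = 1L, x = ctr, y = ctr,
                         r_outer = NA_real_, r_inner = NA_real_,
                         outer = list(outer), inner = list(inner),
                         kind = "polygon")
  }
  axon_set(ax, extent = grid$extent, periodic = FALSE)
}
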