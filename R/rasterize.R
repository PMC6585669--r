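#' Label maps
#'
#' A `label_map` wraps an integer raster with values 0 (extra-axonal),
#' 1 (intra-axonal) and 2 (myelin) on a [grid_spec()], plus (when produced by
#' [rasterize()]) a parallel `axon_id` raster attributing each non-extra pixel
#' to its fiber.
#'
#' @param labels Integer matrix with values in {0, 1, 2}.
#' @param grid The [grid_spec()] the raster lives on.
#' @param axon_id Optional integer matrix of owning axon ids (0 = none).
#' @param axons Optional [axon_set()] the raster was drawn from.
#' @param periodic Whether the raster wraps (toroidal domain).
#' @return A `label_map` object.
#' @export
label_map <- function(labels, grid, axon_id = NULL, axons = NULL,
                      periodic = FALSE) {
  stopifnot(is.matrix(labels))
  vals <- sort(unique(as.integer(labels)))
  if (!all(vals %in% c(0L, 1L, 2L)))
    stop("labels must only contain 0 (extra), 1 (intra), 2 (myelin); found: ",
         paste(setdiff(vals, 0:2), collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(grid = grid, labels = labels, axon_id = axon_id,
                 axons = axons, periodic = isTRUE(periodic)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  fr <- compartment_fractions(x)
  cat(sprintf(
    "<label_map> %d x %d px (%.3g um); extra %.3f / intra %.3f / myelin %.3f\n",
    x$grid$n, ncol(x$labels), x$grid$extent, fr["extra"], fr["intra"],
    fr["myelin"]))
  invisible(x)
}

compartment_fractions <- function(map) {
  cnt <- tabulate(as.integer(map$labels) + 1L, nbins = 3L)
  setNames(cnt / length(map$labels), c("extra", "intra", "myelin"))
}

#' Rasterize an axon set to a label map
#'
#' Pixel labels are assigned by a center-point inclusion test (hard,
#' non-antialiased): a pixel is myelin when its center lies inside the outer
#' boundary but outside the inner one, intra-axonal when inside the inner
#' boundary. Fibers are drawn in id order; a pixel already claimed by an
#' earlier fiber is never overwritten and such collisions are counted in the
#' `collisions` attribute (tangent fibers can share boundary pixels).
#' Periodic axon sets wrap across the raster edges.
#'
#' @param axons An [axon_set()].
#' @param grid A [grid_spec()] whose extent matches the axon-set domain.
#' @return A [label_map()] carrying the `axon_id` raster and the axon set.
#' @export
rasterize <- function(axons, grid) {
  stopifnot(inherits(axons, "axon_set"), inherits(grid, "grid_spec"))
  if (abs(axon_extent(axons) - grid$extent) > 1e-9 * grid$extent)
    stop("grid extent does not match axon-set domain")
  n_px <- grid$n; px <- grid$pixel_size
  periodic <- axon_periodic(axons)
  lab <- matrix(LBL_EXTRA, n_px, n_px)
  ids <- matrix(0L, n_px, n_px)
  collisions <- 0L
  for (k in seq_len(nrow(axons))) {
    hit <- rasterize_one(axons, k, n_px, px, periodic)
    if (is.null(hit)) next
    sub_lab <- lab[hit$ii, hit$jj, drop = FALSE]
    sub_id <- ids[hit$ii, hit$jj, drop = FALSE]
    own <- (hit$myelin | hit$intra)
    taken <- own & sub_id != 0L
    collisions <- collisions + sum(taken)
    claim_my <- hit$myelin & sub_id == 0L
    claim_in <- hit$intra & sub_id == 0L
    sub_lab[claim_my] <- LBL_MYELIN
    sub_lab[claim_in] <- LBL_INTRA
    sub_id[claim_my | claim_in] <- axons$id[k]
    lab[hit$ii, hit$jj] <- sub_lab
    ids[hit$ii, hit$jj] <- sub_id
  }
  out <- label_map(lab, grid, axon_id = ids, axons = axons,
                   periodic = periodic)
  attr(out, "collisions") <- collisions
  if (collisions > 0L)
    message(sprintf("rasterize: %d shared pixel(s) kept their first owner",
                    collisions))
  out
}

# Inclusion masks for one axon over its bounding box.
# Returns wrapped raster indices (ii, jj) and logical masks; NULL if empty.
rasterize_one <- function(axons, k, n_px, px, periodic) {
  if (axons$kind[k] == "circle") {
    ro <- axons$r_outer[k]; ri <- axons$r_inner[k]
    bb <- c(axons$x[k] - ro, axons$x[k] + ro,
            axons$y[k] - ro, axons$y[k] + ro)
  } else {
    po <- axons$outer[[k]]
    if (!polygon_is_closed_simple(po)) stop("axon ", k, ": invalid polygon")
    bb <- c(range(po[, 1]), range(po[, 2]))
  }
  i0 <- floor(bb[1] / px); i1 <- ceiling(bb[2] / px)
  j0 <- floor(bb[3] / px); j1 <- ceiling(bb[4] / px)
  if (!periodic) {
    i0 <- max(i0, 0L); i1 <- min(i1, n_px)
    j0 <- max(j0, 0L); j1 <- min(j1, n_px)
    if (i1 <= i0 || j1 <= j0) return(NULL)
  }
  iseq <- (i0 + 1L):i1; jseq <- (j0 + 1L):j1
  cx <- (iseq - 0.5) * px; cy <- (jseq - 0.5) * px
  if (axons$kind[k] == "circle") {
    dx <- cx - axons$x[k]; dy <- cy - axons$y[k]
    r2 <- outer(dx^2, dy^2, "+")
    myel <- r2 <= ro^2 & r2 > ri^2
    intra <- r2 <= ri^2
  } else {
    pts_x <- rep(cx, times = length(cy))
    pts_y <- rep(cy, each = length(cx))
    in_out <- points_in_polygon(pts_x, pts_y, axons$outer[[k]])
    in_in <- points_in_polygon(pts_x, pts_y, axons$inner[[k]])
    myel <- matrix(in_out & !in_in, length(cx), length(cy))
    intra <- matrix(in_in, length(cx), length(cy))
  }
  ii <- if (periodic) ((iseq - 1L) %% n_px) + 1L else iseq
  jj <- if (periodic) ((jseq - 1L) %% n_px) + 1L else jseq
  list(ii = ii, jj = jj, myelin = myel, intra = intra,
       cx = cx, cy = cy)
}
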