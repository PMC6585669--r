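#' Warp a packed geometry into non-circular outlines
#'
#' Applies a smooth, area-preserving distortion to every boundary vertex:
#' a composition of axis-aligned sinusoidal shear maps
#' (`x <- x + A sin(2 pi f y / L + phase)`, then the same with the axes
#' swapped, over `n_shears` passes with incommensurate frequencies). Each
#' shear has unit Jacobian, so the composition conserves every enclosed
#' area exactly in the continuum limit; per-axon g and whole-map fiber
#' density are therefore conserved (up to polygon discretization), while
#' local shear strain of order `amplitude * 2 pi frequency / L` renders the
#' outlines elliptical/irregular. With integer `frequency` the map is
#' periodic, so toroidal packings stay consistent. An optional radial
#' Gaussian envelope (`decay`, um) confines the distortion; it breaks exact
#' area preservation and is off (`Inf`) by default.
#'
#' @param axons An [axon_set()] (circles are converted to polygons first).
#' @param amplitude Shear displacement amplitude, um.
#' @param frequency Cycles across the domain (integer keeps periodicity);
#'   default `round(extent / 6)`, i.e. a physical wavelength of about 6 um.
#' @param phase Phase offset of the shear waves, radians.
#' @param decay Radial e-folding scale of an optional envelope, um
#'   (`Inf` = none).
#' @param n_shears Number of alternating shear passes.
#' @param n_vertices Vertices used when converting circles to polygons.
#' @param check_collisions Verify that no two outer boundaries intersect
#'   after warping (vertex-in-polygon test between bounding-box neighbors).
#' @return A warped [axon_set()].
#' @export
warp_geometry <- function(axons, amplitude = 0.45, frequency = NULL,
                          phase = 0, decay = Inf, n_shears = 4,
                          n_vertices = 64, check_collisions = TRUE) {
  stopifnot(inherits(axons, "axon_set"), amplitude >= 0)
  L <- axon_extent(axons)
  frequency <- frequency %||% max(1, round(L / 6))
  stopifnot(frequency > 0)
  if (amplitude == 0) return(axons)
  # resolve the shortest displacement wavelength on every boundary
  f_max <- max(1, round(frequency * (1 + (sqrt(5) - 1) / 2 * (n_shears - 1))))
  lambda_min <- L / f_max
  per <- vapply(seq_len(nrow(axons)), function(k) {
    if (axons$kind[k] == "circle") 2 * pi * axons$r_outer[k]
    else polygon_perimeter(axons$outer[[k]])
  }, numeric(1))
  nv <- max(n_vertices, ceiling(max(per) / (lambda_min / 32)))
  ax <- as_polygon_axons(axons, nv)
  warp_fun <- make_shear_warp(L, amplitude, frequency, phase, decay, n_shears)
  for (k in seq_len(nrow(ax))) {
    ax$outer[[k]] <- warp_fun(ax$outer[[k]])
    ax$inner[[k]] <- warp_fun(ax$inner[[k]])
    ctr <- polygon_centroid(ax$outer[[k]])
    ax$x[k] <- ctr[1]; ax$y[k] <- ctr[2]
  }
  ax$r_outer <- NA_real_; ax$r_inner <- NA_real_
  ax <- recompute_axon_measures(ax)
  out <- axon_set(ax, extent = L, periodic = axon_periodic(axons))
  if (check_collisions) {
    bad <- find_outer_collisions(out)
    if (length(bad))
      stop("warp produced intersecting outer boundaries for axon pairs: ",
           paste(vapply(bad, paste, character(1), collapse = "-"),
                 collapse = ", "))
  }
  out
}

# Composition of unit-Jacobian sinusoidal shears; returns a vertex transform.
make_shear_warp <- function(L, amplitude, frequency, phase, decay, n_shears) {
  golden <- (sqrt(5) - 1) / 2
  freqs <- pmax(1, round(frequency * (1 + golden * (seq_len(n_shears) - 1))))
  phases <- phase + (seq_len(n_shears) - 1) * 2.39996
  function(p) {
    x <- p[, 1]; y <- p[, 2]
    for (s in seq_len(n_shears)) {
      kk <- 2 * pi * freqs[s] / L
      env <- if (is.finite(decay)) {
        exp(-(((x - L / 2)^2 + (y - L / 2)^2)) / (2 * decay^2))
      } else 1
      if (s %% 2 == 1) {
        x <- x + amplitude * env * sin(kk * y + phases[s])
      } else {
        y <- y + amplitude * env * sin(kk * x + phases[s])
      }
    }
    cbind(x, y)
  }
}

# Outer-boundary collision scan: bounding-box prefilter, then mutual
# vertex-in-polygon tests (minimum-image aware for periodic sets).
find_outer_collisions <- function(ax) {
  n <- nrow(ax)
  if (n < 2) return(list())
  L <- axon_extent(ax); periodic <- axon_periodic(ax)
  mi <- function(d) if (periodic) d - L * round(d / L) else d
  rad <- vapply(seq_len(n), function(k) {
    p <- ax$outer[[k]]
    sqrt(max((p[, 1] - ax$x[k])^2 + (p[, 2] - ax$y[k])^2))
  }, numeric(1))
  dx <- mi(outer(ax$x, ax$x, "-")); dy <- mi(outer(ax$y, ax$y, "-"))
  d2 <- dx^2 + dy^2
  cand <- which((d2 < outer(rad, rad, "+")^2) & upper.tri(d2))
  bad <- list()
  for (q in cand) {
    i <- ((q - 1L) %% n) + 1L; j <- ((q - 1L) %/% n) + 1L
    pi_ <- ax$outer[[i]]; pj <- ax$outer[[j]]
    if (periodic) {
      # shift j's polygon to i's frame through the minimum image
      sx <- L * round((ax$x[i] - ax$x[j]) / L)
      sy <- L * round((ax$y[i] - ax$y[j]) / L)
      pj <- cbind(pj[, 1] + sx, pj[, 2] + sy)
    }
    if (any(points_in_polygon(pj[, 1], pj[, 2], pi_)) ||
        any(points_in_polygon(pi_[, 1], pi_[, 2], pj)))
      bad[[length(bad) + 1L]] <- c(ax$id[i], ax$id[j])
  }
  bad
}
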