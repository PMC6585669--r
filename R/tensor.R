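#' Build the per-pixel myelin susceptibility tensor map
#'
#' In the local bilayer frame the myelin tensor is
#' `diag(chi_i + chi_a, chi_i - chi_a/2, chi_i - chi_a/2)` (ppb), with the
#' long (anisotropy) axis along the bilayer stacking direction, i.e. radial
#' in the sheath; the anisotropic part is traceless, which is the hollow
#' cylinder convention that yields the intra-axonal shift
#' `(3/4) chi_a ln(1/g) sin^2(theta) f0`. Each myelin pixel's local tensor is
#' rotated about z by its azimuth phi into the common frame; aqueous pixels
#' carry the zero tensor (they are the susceptibility reference).
#'
#' With the rotation by phi the common-frame components are
#' `xx = t + (r - t) cos^2(phi)`, `yy = t + (r - t) sin^2(phi)`,
#' `xy = (r - t) cos(phi) sin(phi)`, `zz = t`, `xz = yz = 0`, where
#' `r = chi_i + chi_a` and `t = chi_i - chi_a/2`.
#'
#' @param map A [label_map()].
#' @param orient An [orientation_map()] covering all myelin pixels.
#' @param props A [compartment_properties()] tibble.
#' @return A `tensor_field` with matrices `xx`, `yy`, `zz`, `xy` (and
#'   implicit zero `xz`, `yz`).
#' @export
build_tensor_map <- function(map, orient, props = compartment_properties()) {
  stopifnot(inherits(map, "label_map"), inherits(orient, "orientation_map"))
  check_same_grid(map$grid, orient$grid)
  my <- map$labels == LBL_MYELIN
  if (any(my & is.na(orient$phi)))
    stop(sum(my & is.na(orient$phi)),
         " myelin pixel(s) have undefined orientation")
  pm <- props_row(props, "myelin")
  chi_r <- pm$chi_iso_ppb + pm$chi_aniso_ppb
  chi_t <- pm$chi_iso_ppb - pm$chi_aniso_ppb / 2
  n_px <- map$grid$n
  xx <- matrix(0, n_px, n_px); yy <- xx; zz <- xx; xy <- xx
  lin <- which(my)
  ph <- orient$phi[lin]
  cp <- cos(ph); sp <- sin(ph)
  xx[lin] <- chi_t + (chi_r - chi_t) * cp * cp
  yy[lin] <- chi_t + (chi_r - chi_t) * sp * sp
  xy[lin] <- (chi_r - chi_t) * cp * sp
  zz[lin] <- chi_t
  structure(list(grid = map$grid, xx = xx, yy = yy, zz = zz, xy = xy,
                 xz = NULL, yz = NULL, periodic = map$periodic),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d px, %d non-zero pixels (ppb)\n",
              x$grid$n, x$grid$n, sum(x$xx != 0 | x$zz != 0)))
  invisible(x)
}

# Extract component matrix, treating NULL as all-zero.
tf_comp <- function(chi, name) {
  m <- chi[[name]]
  if (is.null(m)) matrix(0, chi$grid$n, chi$grid$n) else m
}
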