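#' Compartment properties of the three-pool white-matter model
#'
#' The model distinguishes extra-axonal water, intra-axonal water and myelin.
#' The aqueous compartments are the susceptibility reference (chi = 0); myelin
#' carries an isotropic offset `chi_iso` and an anisotropic component
#' `chi_aniso` arising from the radial stacking of its phospholipid bilayers.
#' Defaults are the literature values used throughout: T2 50/50/15 ms, proton
#' density 1/1/0.5, myelin chi_iso -60 ppb and chi_aniso -120 ppb.
#'
#' @param chi_iso Isotropic myelin susceptibility, ppb.
#' @param chi_aniso Anisotropic myelin susceptibility, ppb.
#' @param T2_myelin,T2_water T2 relaxation times, ms.
#' @param rho_myelin,rho_water Relative proton densities.
#' @return A tibble with one row per compartment (`extra`, `intra`, `myelin`)
#'   and columns `T2_ms`, `rho`, `chi_iso_ppb`, `chi_aniso_ppb`.
#' @examples
#' compartment_properties()
#' compartment_properties(chi_iso = -100, chi_aniso = 0)  # isotropic-only
#' @export
compartment_properties <- function(chi_iso = -60, chi_aniso = -120,
                                   T2_myelin = 15, T2_water = 50,
                                   rho_myelin = 0.5, rho_water = 1) {
  stopifnot(T2_myelin > 0, T2_water > 0, rho_myelin >= 0, rho_water >= 0)
  tibble::tibble(
    compartment = c("extra", "intra", "myelin"),
    T2_ms = c(T2_water, T2_water, T2_myelin),
    rho = c(rho_water, rho_water, rho_myelin),
    chi_iso_ppb = c(0, 0, chi_iso),
    chi_aniso_ppb = c(0, 0, chi_aniso)
  )
}

# Compartment label codes used in every label map.
LBL_EXTRA <- 0L
LBL_INTRA <- 1L
LBL_MYELIN <- 2L

props_row <- function(props, compartment) {
  props[match(compartment, props$compartment), ]
}

#' Static field configuration
#'
#' @param B0 Main field strength, Tesla.
#' @param theta Angle between the fiber long axis (z) and the applied field,
#'   radians. `pi/2` places the field in the cross-sectional plane (along x).
#' @param gamma_bar Reduced gyromagnetic ratio, MHz/T.
#' @return A `field_config` with the unit field direction
#'   `H = c(sin(theta), 0, cos(theta))` and the Larmor frequency `f0_hz`.
#' @export
field_config <- function(B0 = 7, theta = pi / 2, gamma_bar = 42.58) {
  stopifnot(B0 > 0, gamma_bar > 0)
  structure(list(B0 = B0, theta = theta, gamma_bar = gamma_bar,
                 H_hat = c(sin(theta), 0, cos(theta)),
                 f0_hz = gamma_bar * 1e6 * B0),
            class = "field_config")
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf("<field_config> B0 = %g T, theta = %.4g rad, f0 = %.4g MHz\n",
              x$B0, x$theta, x$f0_hz / 1e6))
  invisible(x)
}

#' Echo-time grids
#'
#' Two presets: `"static"` samples 100 points over 0-55 ms (the dense grid
#' used for static-magnetization curves) and `"cuprizone"` mirrors the
#' 13-echo multi-echo GRE protocol (3-55 ms, 4 ms spacing).
#'
#' @param preset `"static"` or `"cuprizone"`, ignored when `times` is given.
#' @param times Optional explicit sample times, ms (strictly increasing).
#' @param t_max Final echo time for the `"static"` preset, ms.
#' @return Numeric vector of echo times in ms.
#' @export
echo_times <- function(preset = c("static", "cuprizone"), times = NULL,
                       t_max = 55) {
  if (!is.null(times)) {
    stopifnot(all(diff(times) > 0), all(times >= 0))
    return(as.numeric(times))
  }
  preset <- match.arg(preset)
  switch(preset,
         static = seq(0, t_max, length.out = 100),
         cuprizone = seq(3, 55, by = 4))
}
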