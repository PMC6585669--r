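#' Synthesize irregular (EM-like) axon outlines
#'
#' Stand-in for a hand-segmented electron-microscopy template: packs circles
#' as in [pack_circles()] and then perturbs each fiber boundary with a random
#' low-order radial harmonic series,
#' `r(theta) = r0 * (1 + sum_h a_h cos(h theta + psi_h))`, h = 2..n_harmonics,
#' with `a_h ~ N(0, amplitude_sd^2 / (n_harmonics - 1))` and the summed
#' modulation clamped to +/- 0.3. The inner boundary is the outer scaled by
#' g, so the g-ratio is preserved exactly; each perturbed outline is rescaled
#' to its original fiber area so the population density and radius statistics
#' match the circular packing. Perturbations that would collide with a
#' neighbor are damped for the offending fibers (factor 0.7 per pass) until
#' the set is collision-free; a fiber damped to (near) zero reverts to its
#' circle. This file is synthetic data: it emulates outline irregularity
#' only, not any measured micrograph.
#'
#' @param config A [packing_config()]; `min_gap` should leave room for the
#'   bulges (the default used here is 0.06 um when the config keeps its own
#'   default of 0.02).
#' @param roughness List with `n_harmonics` (highest harmonic order) and
#'   `amplitude_sd` (total relative radial standard deviation, < 0.3).
#' @param seed RNG seed for the harmonic draws (the packing uses
#'   `config$seed`).
#' @param n_vertices Boundary vertices per fiber.
#' @return An [axon_set()] of polygonal fibers (periodic).
#' @export
synthesize_irregular_axons <- function(config,
                                       roughness = list(n_harmonics = 5,
                                                        amplitude_sd = 0.15),
                                       seed = config$seed + 1L,
                                       n_vertices = 64) {
  stopifnot(inherits(config, "packing_config"))
  H <- roughness$n_harmonics %||% 5L
  amp <- roughness$amplitude_sd %||% 0.15
  stopifnot(H >= 2, amp >= 0, amp < 0.3)
  if (config$min_gap < 0.05 && amp > 0)
    config$min_gap <- 0.06
  base <- pack_circles(config)
  if (amp == 0) return(base)
  n <- nrow(base)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  coef <- with_seed(seed, {
    list(a = matrix(rnorm(n * (H - 1), 0, amp / sqrt(H - 1)), n, H - 1),
         psi = matrix(runif(n * (H - 1), 0, 2 * pi), n, H - 1))
  })
  damp <- rep(1, n)
  g <- base$r_inner / base$r_outer
  build <- function() {
    ax <- base
    for (k in seq_len(n)) {
      mod <- rep(0, n_vertices)
      for (h in 2:H)
        mod <- mod + coef$a[k, h - 1] * cos(h * th + coef$psi[k, h - 1])
      mod <- pmax(pmin(damp[k] * mod, 0.3), -0.3)
      r_out <- base$r_outer[k] * (1 + mod)
      # rescale to conserve the fiber area of the unperturbed circle
      area <- polygon_area(cbind(r_out * cos(th), r_out * sin(th)))
      r_out <- r_out * sqrt(pi * base$r_outer[k]^2 / area)
      outer <- cbind(base$x[k] + r_out * cos(th),
                     base$y[k] + r_out * sin(th))
      inner <- cbind(base$x[k] + g[k] * r_out * cos(th),
                     base$y[k] + g[k] * r_out * sin(th))
      ax$outer[[k]] <- outer; ax$inner[[k]] <- inner
    }
    ax$kind <- "polygon"
    ax$r_outer <- NA_real_; ax$r_inner <- NA_real_
    axon_set(recompute_axon_measures(ax), extent = axon_extent(base),
             periodic = TRUE)
  }
  out <- build()
  for (pass in seq_len(12L)) {
    bad <- find_outer_collisions(out)
    if (!length(bad)) break
    ids <- unique(unlist(bad))
    damp[ids] <- damp[ids] * 0.7
    damp[damp < 0.05] <- 0
    out <- build()
  }
  if (length(find_outer_collisions(out)))
    stop("irregular synthesis could not resolve boundary collisions")
  out
}
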