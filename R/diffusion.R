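#' Monte Carlo diffusion configuration
#'
#' Spins random-walk in two dimensions through the field map with free
#' diffusivity `D_free` in the aqueous compartments; myelin water is
#' immobile (`D_myelin = 0`). The default step time follows the
#' four-pixel rule `step_time = (4 * pixel_size)^2 / (4 * D_free)` so a step
#' stays small relative to the inter-fiber spacing; `time_scale` coarsens it
#' (scaled-down runs) with the step count adjusted to cover `t_max`.
#'
#' @param n_spins Number of spins.
#' @param D_free Aqueous diffusion coefficient, um^2/ms (2 matches
#'   measurements along axons).
#' @param step_time Step duration, ms; `NULL` applies the four-pixel rule at
#'   [run_diffusion()] time.
#' @param n_steps Number of steps; `NULL` derives it from `t_max`.
#' @param t_max Total simulated time, ms.
#' @param time_scale Multiplier applied to an automatic `step_time`.
#' @param seed RNG seed.
#' @param boundary `"reject"` (a step into myelin or off a bounded grid is
#'   discarded; the spin stays put for that step) or `"reflect"`.
#' @param myelin_spins `"immobile"` seeds myelin water as stationary spins
#'   accruing local phase; `"exclude"` seeds no spins in myelin and adds the
#'   myelin term of the static signal analytically.
#' @return A `diffusion_config` list.
#' @export
diffusion_config <- function(n_spins = 10000, D_free = 2, step_time = NULL,
                             n_steps = NULL, t_max = 55, time_scale = 1,
                             seed = 1L,
                             boundary = c("reject", "reflect"),
                             myelin_spins = c("immobile", "exclude")) {
  stopifnot(n_spins >= 1, D_free > 0, t_max > 0, time_scale > 0)
  structure(list(n_spins = as.integer(n_spins), D_free = D_free,
                 D_myelin = 0, step_time = step_time, n_steps = n_steps,
                 t_max = t_max, time_scale = time_scale,
                 seed = as.integer(seed),
                 boundary = match.arg(boundary),
                 myelin_spins = match.arg(myelin_spins)),
            class = "diffusion_config")
}

resolve_steps <- function(cfg, grid) {
  dt <- cfg$step_time %||%
    ((4 * grid$pixel_size)^2 / (4 * cfg$D_free) * cfg$time_scale)
  ns <- cfg$n_steps %||% ceiling(cfg$t_max / dt)
  list(dt = dt, n_steps = as.integer(ns))
}

#' Seed a spin ensemble
#'
#' Spins are placed uniformly at random over masked pixels of all
#' compartments (uniform in area, like the spin density of Eq. 2's integral),
#' weighted by the proton density of their home compartment. Myelin-seeded
#' spins are flagged immobile. Deterministic given `cfg$seed`.
#'
#' @param map A [label_map()].
#' @param mask A [sample_mask()] restricting the seeded region.
#' @param cfg A [diffusion_config()].
#' @param props [compartment_properties()].
#' @return A `spin_ensemble`: list of vectors `x`, `y` (um), `phase` (rad),
#'   `home` (label), `weight`, `mobile`.
#' @export
init_spins <- function(map, mask = NULL, cfg = diffusion_config(),
                       props = compartment_properties()) {
  stopifnot(inherits(map, "label_map"))
  mask <- mask %||% sample_mask(map$grid)
  check_same_grid(map$grid, mask$grid)
  sel <- which(mask$mask)
  if (!length(sel)) stop("empty sample mask")
  if (cfg$myelin_spins == "exclude")
    sel <- sel[map$labels[sel] != LBL_MYELIN]
  n_px <- map$grid$n; px <- map$grid$pixel_size
  with_seed(cfg$seed, {
    pick <- sel[sample.int(length(sel), cfg$n_spins, replace = TRUE)]
    ii <- ((pick - 1L) %% n_px) + 1L
    jj <- ((pick - 1L) %/% n_px) + 1L
    x <- (ii - 1L + runif(cfg$n_spins)) * px
    y <- (jj - 1L + runif(cfg$n_spins)) * px
    home <- map$labels[pick]
    rho <- props$rho[match(c("extra", "intra", "myelin"), props$compartment)]
    structure(list(x = x, y = y, phase = numeric(cfg$n_spins),
                   home = home, weight = rho[home + 1L],
                   mobile = home != LBL_MYELIN, t = 0),
              class = "spin_ensemble")
  })
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d spins (%d mobile) at t = %.3g ms\n",
              length(x$x), sum(x$mobile), x$t))
  invisible(x)
}

#' Advance a spin ensemble by one step
#'
#' Mobile spins take an isotropic Gaussian displacement with per-axis
#' standard deviation `sqrt(2 D_free dt)`. A step landing in myelin (or off a
#' bounded grid) is handled by the boundary rule; on a periodic map positions
#' wrap. After moving, each spin accrues `sign * 2 pi * df(position) * dt`.
#' Exposed mainly for testing; [run_diffusion()] drives the full walk.
#'
#' @param spins A `spin_ensemble`.
#' @param map A [label_map()].
#' @param field The matching `field_map`.
#' @param cfg A [diffusion_config()].
#' @param dt Step duration, ms (resolved from `cfg` when `NULL`).
#' @param sign_convention Phase sign.
#' @return The advanced `spin_ensemble`.
#' @export
step_ensemble <- function(spins, map, field, cfg, dt = NULL,
                          sign_convention = 1) {
  dt <- dt %||% resolve_steps(cfg, map$grid)$dt
  n_px <- map$grid$n; px <- map$grid$pixel_size
  L <- map$grid$extent
  mob <- spins$mobile
  nm <- sum(mob)
  if (nm) {
    sdv <- sqrt(2 * cfg$D_free * dt)
    nx <- spins$x[mob] + rnorm(nm, 0, sdv)
    ny <- spins$y[mob] + rnorm(nm, 0, sdv)
    if (map$periodic) {
      nx <- nx %% L; ny <- ny %% L
      ok_dom <- rep(TRUE, nm)
    } else {
      ok_dom <- nx >= 0 & nx < L & ny >= 0 & ny < L
    }
    ii <- pmin(pmax(floor(nx / px), 0), n_px - 1) + 1L
    jj <- pmin(pmax(floor(ny / px), 0), n_px - 1) + 1L
    land <- map$labels[(jj - 1L) * n_px + ii]
    ok <- ok_dom & land != LBL_MYELIN
    if (cfg$boundary == "reject") {
      idx <- which(mob)[ok]
      spins$x[idx] <- nx[ok]; spins$y[idx] <- ny[ok]
    } else {
      # reflect: retry rejected steps with mirrored displacement about the
      # current position (single bounce; repeated failure leaves spin put)
      idx <- which(mob)[ok]
      spins$x[idx] <- nx[ok]; spins$y[idx] <- ny[ok]
      bad <- which(mob)[!ok]
      if (length(bad)) {
        rx <- 2 * spins$x[bad] - nx[!ok]
        ry <- 2 * spins$y[bad] - ny[!ok]
        if (map$periodic) { rx <- rx %% L; ry <- ry %% L }
        okd <- if (map$periodic) rep(TRUE, length(bad)) else
          rx >= 0 & rx < L & ry >= 0 & ry < L
        i2 <- pmin(pmax(floor(rx / px), 0), n_px - 1) + 1L
        j2 <- pmin(pmax(floor(ry / px), 0), n_px - 1) + 1L
        ok2 <- okd & map$labels[(j2 - 1L) * n_px + i2] != LBL_MYELIN
        spins$x[bad[ok2]] <- rx[ok2]; spins$y[bad[ok2]] <- ry[ok2]
      }
    }
  }
  ii <- pmin(pmax(floor(spins$x / px), 0), n_px - 1) + 1L
  jj <- pmin(pmax(floor(spins$y / px), 0), n_px - 1) + 1L
  df <- field$delta_f[(jj - 1L) * n_px + ii]
  spins$phase <- spins$phase + sign_convention * 2 * pi * df * dt / 1000
  spins$t <- spins$t + dt
  spins
}

#' Run a Monte Carlo diffusion simulation
#'
#' Walks the ensemble over the field, records per-spin phase at each echo
#' time (linear interpolation between the bracketing steps) and synthesizes
#' the diffusion-weighted signal
#' `S(t) = sum_spins weight * exp(-t / T2_home) * exp(i phase(t))`,
#' normalized like the static signal. In the `D -> 0` limit this converges
#' to a Monte Carlo estimate of [static_signal()].
#'
#' @param map A [label_map()].
#' @param field The matching `field_map`.
#' @param cfg A [diffusion_config()].
#' @param props [compartment_properties()].
#' @param echoes Echo times, ms (all within the simulated duration).
#' @param mask [sample_mask()] for spin seeding.
#' @param sign_convention Phase sign.
#' @return A `wm_signal` with the Monte Carlo settings in its metadata and
#'   the final `spin_ensemble` in attribute `"ensemble"`.
#' @export
run_diffusion <- function(map, field, cfg = diffusion_config(),
                          props = compartment_properties(),
                          echoes = echo_times("static"), mask = NULL,
                          sign_convention = 1) {
  stopifnot(inherits(map, "label_map"), inherits(field, "field_map"))
  check_same_grid(map$grid, field$grid)
  rs <- resolve_steps(cfg, map$grid)
  if (max(echoes) > rs$dt * rs$n_steps + 1e-9)
    stop(sprintf("echo at %.3g ms beyond simulated duration %.3g ms",
                 max(echoes), rs$dt * rs$n_steps))
  mask <- mask %||% sample_mask(map$grid)
  spins <- init_spins(map, mask, cfg, props)
  n_spins <- length(spins$x)
  phases <- matrix(0, n_spins, length(echoes))
  with_seed(cfg$seed + 1L, {
    prev_phase <- spins$phase
    prev_t <- 0
    eix <- 1L
    while (eix <= length(echoes) && echoes[eix] <= 0) {
      phases[, eix] <- spins$phase
      eix <- eix + 1L
    }
    for (k in seq_len(rs$n_steps)) {
      spins <- step_ensemble(spins, map, field, cfg, rs$dt, sign_convention)
      while (eix <= length(echoes) && echoes[eix] <= spins$t + 1e-12) {
        wgt <- (echoes[eix] - prev_t) / (spins$t - prev_t)
        phases[, eix] <- prev_phase + wgt * (spins$phase - prev_phase)
        eix <- eix + 1L
      }
      if (eix > length(echoes)) break
      prev_phase <- spins$phase
      prev_t <- spins$t
    }
  })
  S <- diffusion_signal(phases, spins, props, echoes)
  if (cfg$myelin_spins == "exclude")
    S <- add_static_myelin_term(S, map, field, mask, props, echoes,
                                sign_convention, length(spins$x))
  attr(S, "ensemble") <- spins
  meta <- attr(S, "meta")
  meta$kind <- "diffusion"
  meta$n_spins <- n_spins
  meta$step_time_ms <- rs$dt
  meta$n_steps <- rs$n_steps
  meta$seed <- cfg$seed
  attr(S, "meta") <- meta
  S
}

#' Synthesize the signal from recorded spin phases
#'
#' @param phases Matrix of per-spin phases (spins x echoes), rad.
#' @param spins The `spin_ensemble` providing weights and home compartments.
#' @param props [compartment_properties()].
#' @param echoes Echo times, ms.
#' @return A `wm_signal`.
#' @export
diffusion_signal <- function(phases, spins, props = compartment_properties(),
                             echoes = echo_times("static")) {
  stopifnot(is.matrix(phases), nrow(phases) == length(spins$x),
            ncol(phases) == length(echoes))
  T2 <- props$T2_ms[match(c("extra", "intra", "myelin"), props$compartment)]
  t2_home <- T2[spins$home + 1L]
  S <- vapply(seq_along(echoes), function(k) {
    env <- spins$weight * exp(-echoes[k] / t2_home)
    sum(env * exp(1i * phases[, k]))
  }, complex(1))
  new_wm_signal(echoes, S / sum(spins$weight),
                meta = list(kind = "diffusion"))
}

# Recombine an aqueous-only Monte Carlo signal with the static (immobile)
# myelin pixel sum, area-weighted so the normalization matches Eq. 2.
add_static_myelin_term <- function(S, map, field, mask, props, echoes,
                                   sign_convention, n_spins) {
  sel <- mask$mask
  lb <- map$labels[sel]
  f_my <- field$delta_f[sel][lb == LBL_MYELIN]
  n_aq <- sum(lb != LBL_MYELIN)
  pm <- props_row(props, "myelin")
  rho_aq <- props$rho[match(c("extra", "intra"), props$compartment)]
  w_aq_total <- sum(rho_aq * c(sum(lb == LBL_EXTRA), sum(lb == LBL_INTRA)))
  z_aq <- complex(real = S$real, imaginary = S$imag) * w_aq_total
  z_my <- vapply(echoes, function(t)
    pm$rho * exp(-t / pm$T2_ms) *
      sum(exp(1i * sign_convention * 2 * pi * f_my * t / 1000)),
    complex(1))
  S0 <- w_aq_total + pm$rho * length(f_my)
  new_wm_signal(echoes, (z_aq + z_my) / S0, meta = attr(S, "meta"))
}
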