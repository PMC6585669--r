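#' Experiment configuration
#'
#' Bundles the knobs shared by the experiment drivers. Each driver derives
#' deterministic child seeds from `seed` for its stochastic stages and
#' records every parameter in the result's `meta`, so deterministic stages
#' re-run bit-identically.
#'
#' @param seed Master seed.
#' @param grid_n Raster resolution for packed models (pixels per side).
#' @param extent Domain side, um.
#' @param n_axons,gamma_shape,g_ratio,min_gap Packing parameters
#'   (see [packing_config()]).
#' @param mean_radius Mean outer radius, um (`NULL` = calibrated).
#' @param props [compartment_properties()].
#' @param field [field_config()].
#' @param mask_fraction Sampled area fraction.
#' @param echoes Echo times, ms.
#' @param reference Field referencing rule passed to [reference_field()].
#' @param sign_convention Phase sign.
#' @param offset_hz Uniform frequency offset (nonlocal-field hook), Hz.
#' @param g_levels g-ratio ladder for demyelination sweeps.
#' @param diffusion `NULL` or a [diffusion_config()] to add diffusion runs.
#' @param freq_bin Frequency compression for [static_signal()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L, grid_n = 2227, extent = 37,
                              n_axons = 1434, gamma_shape = 5.7,
                              g_ratio = 0.7, min_gap = 0.02,
                              mean_radius = NULL,
                              props = compartment_properties(),
                              field = field_config(),
                              mask_fraction = 0.5,
                              echoes = echo_times("static"),
                              reference = "extra_mean",
                              sign_convention = 1,
                              offset_hz = 0,
                              g_levels = seq(0.70, 0.98, length.out = 9),
                              diffusion = NULL,
                              freq_bin = NULL) {
  stopifnot(all(diff(g_levels) > 0), all(g_levels > 0 & g_levels < 1))
  structure(as.list(environment()), class = "experiment_config")
}

exp_packing <- function(cfg, seed) {
  packing_config(n_axons = cfg$n_axons, gamma_shape = cfg$gamma_shape,
                 mean_radius = cfg$mean_radius, g_ratio = cfg$g_ratio,
                 min_gap = cfg$min_gap, seed = seed, extent = cfg$extent)
}

# Shared field -> (histogram, signal) stage.
field_and_signal <- function(map, cfg, axons = NULL, label = NULL) {
  orient <- orientation_map(map, axons)
  chi <- build_tensor_map(map, orient, cfg$props)
  fld <- forward_field(chi, cfg$field)
  rm(chi)
  fld <- reference_field(fld, map, method = cfg$reference)
  if (cfg$offset_hz != 0) fld <- apply_uniform_offset(fld, cfg$offset_hz)
  mask <- sample_mask(map$grid, cfg$mask_fraction)
  hist <- compartment_histograms(fld, map, mask)
  sig <- static_signal(fld, map, cfg$props, cfg$echoes, mask,
                       cfg$sign_convention, cfg$freq_bin)
  list(field = fld, mask = mask, histogram = hist, signal = sig,
       label = label)
}

new_wm_sweep <- function(signals, histograms, measurements, meta) {
  structure(list(signals = signals, histograms = histograms,
                 measurements = measurements, meta = meta),
            class = "wm_sweep")
}

#' @export
print.wm_sweep <- function(x, ...) {
  cat(sprintf("<wm_sweep> %s: %d run(s)\n", x$meta$experiment %||% "?",
              length(unique(x$signals$run))))
  invisible(x)
}

#' @method tidy wm_sweep
#' @export
tidy.wm_sweep <- function(x, ...) x$signals

#' @method glance wm_sweep
#' @export
glance.wm_sweep <- function(x, ...) {
  x$signals |>
    dplyr::group_by(run, mode) |>
    dplyr::summarise(
      t_max_ms = max(time_ms),
      magnitude_final = magnitude[which.max(time_ms)],
      phase_final_rad = phase_rad[which.max(time_ms)],
      .groups = "drop")
}

#' Single-axon suite: eccentricity and rotation series
#'
#' Field maps and static signals for one myelinated axon of elliptical
#' cross-section at each eccentricity (areas conserved across cases), plus
#' in-plane rotations of the most eccentric case from orthogonal to parallel
#' to the transverse field projection.
#'
#' @param cfg An [experiment_config()]; the reference grid for this suite is
#'   500 px over 3 um, set via `cfg$grid_n`/`cfg$extent` or the defaults
#'   here.
#' @param eccentricities Eccentricity ladder.
#' @param rotations Rotation angles (rad) applied to the most eccentric case.
#' @param r_equiv Area-equivalent outer radius, um.
#' @return A `wm_sweep` with one run per case.
#' @export
run_single_axon_suite <- function(cfg = experiment_config(grid_n = 500,
                                                          extent = 3),
                                  eccentricities = c(0, 0.66, 0.80, 0.87),
                                  rotations = c(pi / 4, pi / 2),
                                  r_equiv = 0.5) {
  grid <- grid_spec(cfg$grid_n, cfg$extent)
  cases <- c(
    lapply(eccentricities, function(e) list(e = e, rot = 0)),
    lapply(rotations, function(r) list(e = max(eccentricities), rot = r)))
  runs <- lapply(cases, function(cs) {
    ax <- make_single_ellipse_axon(ellipse_spec(cs$e, rotation = cs$rot),
                                   g = cfg$g_ratio, grid = grid,
                                   r_equiv = r_equiv)
    map <- rasterize(ax, grid)
    fs <- field_and_signal(map, cfg, ax)
    label <- sprintf("e=%.2f rot=%.2f", cs$e, cs$rot)
    list(label = label, e = cs$e, rot = cs$rot, fs = fs,
         meas = measure(map))
  })
  collect_sweep(runs, "single_axon", cfg,
                extra_cols = function(r) tibble::tibble(eccentricity = r$e,
                                                        rotation = r$rot))
}

#' Three-geometry comparison: circular, warped, irregular
#'
#' Builds the packed circular model, its warped (packed-ellipse) counterpart
#' and an irregular synthetic geometry under matched compartment properties,
#' then computes frequency histograms and static signals for each.
#'
#' @param cfg An [experiment_config()].
#' @param geometries Which of the three geometries to run.
#' @param n_irregular Fiber count for the irregular model (the EM template
#'   has 602 fibers; its domain is scaled to keep the same composition).
#' @return A `wm_sweep` (runs keyed "circular", "warped", "irregular").
#' @export
run_geometry_comparison <- function(cfg = experiment_config(),
                                    geometries = c("circular", "warped",
                                                   "irregular"),
                                    n_irregular = 602) {
  grid <- grid_spec(cfg$grid_n, cfg$extent)
  base <- pack_circles(exp_packing(cfg, child_seed(cfg$seed, 1L)), grid)
  runs <- list()
  for (geo in geometries) {
    if (geo == "circular") {
      ax <- base; g_grid <- grid
    } else if (geo == "warped") {
      ax <- warp_geometry(base); g_grid <- grid
    } else {
      scale <- sqrt(n_irregular / cfg$n_axons)
      ext_irr <- cfg$extent * scale
      g_grid <- grid_spec(round(cfg$grid_n * scale), ext_irr)
      pc <- packing_config(n_axons = n_irregular,
                           gamma_shape = cfg$gamma_shape,
                           mean_radius = cfg$mean_radius,
                           g_ratio = cfg$g_ratio, min_gap = cfg$min_gap,
                           seed = child_seed(cfg$seed, 2L),
                           extent = ext_irr, match_fraction = TRUE)
      ax <- synthesize_irregular_axons(pc)
    }
    map <- rasterize(ax, g_grid)
    fs <- field_and_signal(map, cfg, ax)
    runs[[geo]] <- list(label = geo, fs = fs, meas = measure(map))
  }
  collect_sweep(runs, "geometry_comparison", cfg)
}

#' Demyelination sweep
#'
#' Erodes the myelin of a packed circular geometry to each g-ratio in
#' `cfg$g_levels` (thinning from the inside out; outer boundaries and fiber
#' density unchanged) and computes the static — and optionally
#' diffusion-weighted — signal for each stage.
#'
#' @param cfg An [experiment_config()]; set `cfg$diffusion` to a
#'   [diffusion_config()] to add diffusion runs.
#' @param axons Optional pre-built circular [axon_set()] (built from `cfg`
#'   when omitted). Its g must not exceed `min(cfg$g_levels)`.
#' @return A `wm_sweep` with one run per (g, mode); `summary` in `meta`
#'   tabulates magnitude and |phase| at the final echo versus g.
#' @export
run_demyelination_sweep <- function(cfg = experiment_config(), axons = NULL) {
  grid <- grid_spec(cfg$grid_n, cfg$extent)
  axons <- axons %||% pack_circles(exp_packing(cfg, child_seed(cfg$seed, 1L)))
  if (any(axons$g > min(cfg$g_levels) + 1e-9))
    stop("base geometry g exceeds the smallest sweep level")
  runs <- list()
  for (gi in seq_along(cfg$g_levels)) {
    g <- cfg$g_levels[gi]
    ax_g <- erode_myelin(axons, g)
    map <- rasterize(ax_g, grid)
    fs <- field_and_signal(map, cfg, ax_g)
    key <- sprintf("g=%.3f", g)
    runs[[key]] <- list(label = key, g = g, fs = fs, meas = measure(map))
    if (!is.null(cfg$diffusion)) {
      dcfg <- cfg$diffusion
      dcfg$seed <- child_seed(cfg$seed, 100L + gi)
      dsig <- run_diffusion(map, fs$field, dcfg, cfg$props, cfg$echoes,
                            fs$mask, cfg$sign_convention)
      runs[[key]]$diffusion_signal <- dsig
    }
  }
  collect_sweep(runs, "demyelination_sweep", cfg,
                extra_cols = function(r) tibble::tibble(g = r$g))
}

#' Susceptibility variants
#'
#' Re-runs a pipeline with substituted susceptibility values:
#' `"isotropic_only"` sets chi_iso = -100 ppb, chi_aniso = 0;
#' `"alt_chi"` sets chi_iso = -60 ppb, chi_aniso = -70 ppb. Geometry and all
#' other parameters are untouched, so differences are attributable to the
#' susceptibility model alone.
#'
#' @param cfg An [experiment_config()].
#' @param variant `"isotropic_only"` or `"alt_chi"`.
#' @param axons Optional pre-built [axon_set()] shared with the baseline.
#' @return A `wm_sweep` with a single run.
#' @export
run_variant <- function(cfg = experiment_config(),
                        variant = c("isotropic_only", "alt_chi"),
                        axons = NULL) {
  variant <- match.arg(variant)
  cfg$props <- switch(variant,
                      isotropic_only = compartment_properties(chi_iso = -100,
                                                              chi_aniso = 0),
                      alt_chi = compartment_properties(chi_iso = -60,
                                                       chi_aniso = -70))
  grid <- grid_spec(cfg$grid_n, cfg$extent)
  axons <- axons %||% pack_circles(exp_packing(cfg, child_seed(cfg$seed, 1L)))
  map <- rasterize(axons, grid)
  fs <- field_and_signal(map, cfg, axons)
  runs <- list(list(label = variant, fs = fs, meas = measure(map)))
  collect_sweep(runs, paste0("variant_", variant), cfg)
}

# Assemble sweep tibbles from per-run results.
collect_sweep <- function(runs, experiment, cfg, extra_cols = NULL) {
  sig_rows <- list(); hist_rows <- list(); meas_rows <- list()
  for (r in runs) {
    ex <- if (is.null(extra_cols)) tibble::tibble(.rows = 1) else
      extra_cols(r)
    s <- tibble::as_tibble(r$fs$signal)
    sig_rows[[length(sig_rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(run = r$label, mode = "static"),
                       ex[rep(1, nrow(s)), , drop = FALSE], s)
    if (!is.null(r$diffusion_signal)) {
      d <- tibble::as_tibble(r$diffusion_signal)
      sig_rows[[length(sig_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(run = r$label, mode = "diffusion"),
                         ex[rep(1, nrow(d)), , drop = FALSE], d)
    }
    h <- r$fs$histogram$peaks
    hist_rows[[length(hist_rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(run = r$label), h)
    m <- glance(r$meas)
    meas_rows[[length(meas_rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(run = r$label), m)
  }
  signals <- dplyr::bind_rows(sig_rows)
  meta <- list(experiment = experiment, config = cfg,
               summary = signals |>
                 dplyr::group_by(run, mode) |>
                 dplyr::summarise(
                   magnitude_final = magnitude[which.max(time_ms)],
                   abs_phase_final = abs(phase_rad[which.max(time_ms)]),
                   .groups = "drop"))
  new_wm_sweep(signals, dplyr::bind_rows(hist_rows),
               dplyr::bind_rows(meas_rows), meta)
}
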