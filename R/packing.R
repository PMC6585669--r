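#' Packing configuration for polydisperse circular fibers
#'
#' Outer fiber radii are drawn from a Gamma distribution with shape
#' `gamma_shape` and mean `mean_radius` (scale = mean/shape); the inner
#' (axonal) radius is `g_ratio` times the outer radius. The template the
#' packing emulates is a segmented electron micrograph of mouse white matter:
#' gamma-shaped radius distribution (shape 5.7), g-ratio 0.7, and a rendered
#' compartment composition of roughly 36% extra-axonal space, 32% myelin and
#' 31% intra-axonal space.
#'
#' When `mean_radius` is `NULL` it is calibrated so that the expected fiber
#' area fraction equals `1 - target_evf`:
#' `mean = sqrt((1 - target_evf) * extent^2 * shape / ((shape + 1) * n * pi))`.
#' With the defaults this gives 0.4067 um. The calibration pins the
#' compartment volume fractions, which are what the susceptibility field and
#' signal depend on (see the methods vignette for the reasoning).
#'
#' @param n_axons Number of fibers.
#' @param gamma_shape Gamma shape parameter of the outer-radius distribution.
#' @param mean_radius Mean outer radius, um, or `NULL` to calibrate from
#'   `target_evf`.
#' @param g_ratio Target g-ratio (inner/outer radius).
#' @param min_gap Minimum clearance between fiber boundaries, um.
#' @param seed RNG seed (packing is deterministic given the seed).
#' @param max_iterations Total relaxation-sweep budget before the packing is
#'   declared failed.
#' @param extent Domain side length, um.
#' @param target_evf Extra-axonal volume fraction used to calibrate
#'   `mean_radius` when the latter is `NULL`.
#' @param match_fraction If `TRUE`, rescale the drawn radii (gamma is a scale
#'   family, so the distribution shape is preserved) so the realized fiber
#'   area fraction equals `1 - target_evf` exactly; used when a geometry must
#'   match a companion model's fiber density, as companion geometries in a
#'   matched comparison must be.
#' @return A `packing_config` list.
#' @export
packing_config <- function(n_axons = 1434, gamma_shape = 5.7,
                           mean_radius = NULL, g_ratio = 0.7,
                           min_gap = 0.02, seed = 1L,
                           max_iterations = 60000L, extent = 37,
                           target_evf = 0.36, match_fraction = FALSE) {
  stopifnot(gamma_shape > 0, g_ratio > 0, g_ratio < 1, n_axons >= 1,
            extent > 0, min_gap >= 0)
  if (is.null(mean_radius)) {
    mean_radius <- sqrt((1 - target_evf) * extent^2 * gamma_shape /
                          ((gamma_shape + 1) * n_axons * pi))
  }
  stopifnot(mean_radius > 0)
  structure(list(n_axons = as.integer(n_axons), gamma_shape = gamma_shape,
                 mean_radius = mean_radius, g_ratio = g_ratio,
                 min_gap = min_gap, seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 extent = extent, target_evf = target_evf,
                 match_fraction = isTRUE(match_fraction)),
            class = "packing_config")
}

#' Random close packing of gamma-distributed circles
#'
#' Places `n_axons` non-overlapping circular fibers in a periodic square
#' domain by random sequential placement followed by staged radius growth
#' with collision-resolving relaxation: radii start scaled down, overlapping
#' pairs are pushed apart along their center line (with a small positional
#' jitter that breaks symmetric deadlocks), and the radii are grown toward
#' full size once the current stage is overlap-free. The result is a
#' disordered, contact-rich packing; its acceptance criterion is the achieved
#' compartment composition, not any particular contact statistics.
#'
#' @param config A [packing_config()].
#' @param grid Optional [grid_spec()]; when given its extent overrides
#'   `config$extent` (the grid resolution itself only matters at
#'   rasterization time).
#' @return An [axon_set()] of circular fibers (periodic).
#' @examples
#' ax <- pack_circles(packing_config(n_axons = 40, extent = 8, seed = 2))
#' @export
pack_circles <- function(config, grid = NULL) {
  stopifnot(inherits(config, "packing_config"))
  L <- if (!is.null(grid)) grid$extent else config$extent
  n <- config$n_axons
  exp_area <- n * pi * config$mean_radius^2 *
    (config$gamma_shape + 1) / config$gamma_shape
  if (exp_area >= 0.9 * L^2)
    stop(sprintf(paste0("requested packing is too dense: expected fiber area ",
                        "%.1f um^2 exceeds 90%% of the %.1f um^2 domain"),
                 exp_area, L^2))
  res <- with_seed(config$seed,
                   relax_pack(n, L, config$gamma_shape, config$mean_radius,
                              config$min_gap, config$max_iterations,
                              if (config$match_fraction)
                                (1 - config$target_evf) * L^2 else NULL))
  ax <- tibble::tibble(
    id = seq_len(n), x = res$x, y = res$y,
    r_outer = res$r, r_inner = config$g_ratio * res$r,
    outer = vector("list", n), inner = vector("list", n),
    kind = "circle")
  axon_set(ax, extent = L, periodic = TRUE)
}

# Core relaxation packer (toroidal domain). Deterministic under the caller's
# RNG state.
relax_pack <- function(n, L, shape, mean_r, gap, max_sweeps,
                       match_area = NULL) {
  r_full <- sort(rgamma(n, shape = shape, scale = mean_r / shape),
                 decreasing = TRUE)
  if (!is.null(match_area))
    r_full <- r_full * sqrt(match_area / sum(pi * r_full^2))
  if (2 * max(r_full) + gap >= L)
    stop("largest fiber does not fit in the domain")
  x <- runif(n, 0, L); y <- runif(n, 0, L)
  if (n == 1L) return(list(x = x, y = y, r = r_full))
  ut <- upper.tri(matrix(0, n, n))
  mi <- function(d) d - L * round(d / L)
  pairs_within <- function(x, y, r, margin) {
    dx <- mi(outer(x, x, "-")); dy <- mi(outer(y, y, "-"))
    d2 <- dx * dx + dy * dy
    cand <- which((d2 < (outer(r, r, "+") + margin)^2) & ut)
    cbind(((cand - 1L) %% n) + 1L, ((cand - 1L) %/% n) + 1L)
  }
  total <- 0L
  frac_full <- sum(pi * r_full^2) / L^2
  scale <- min(1, sqrt(0.3 / frac_full))
  repeat {
    r <- r_full * scale
    prs <- NULL; need <- NULL; rebuild <- TRUE; scount <- 0L; done <- FALSE
    for (s in seq_len(5000L)) {
      total <- total + 1L
      if (total > max_sweeps)
        stop(sprintf(paste0("packing failed after %d sweeps: %d fibers placed ",
                            "at scale %.3f (fiber area fraction %.3f)"),
                     total, n, scale, sum(pi * r^2) / L^2))
      if (rebuild) {
        prs <- pairs_within(x, y, r, gap + 0.45)
        need <- r[prs[, 1]] + r[prs[, 2]] + gap
        rebuild <- FALSE; scount <- 0L
      }
      dx <- mi(x[prs[, 1]] - x[prs[, 2]])
      dy <- mi(y[prs[, 1]] - y[prs[, 2]])
      d <- sqrt(dx * dx + dy * dy)
      ov <- which(d < need)
      if (!length(ov)) {
        if (nrow(pairs_within(x, y, r, 0)) == 0L) { done <- TRUE; break }
        rebuild <- TRUE; next
      }
      i <- prs[ov, 1]; j <- prs[ov, 2]
      dd <- pmax(d[ov], 1e-6)
      step <- pmin((need[ov] - d[ov]) * 0.55, 0.2)
      idvec <- c(i, j)
      axm <- rowsum(c(dx[ov] / dd * step, -dx[ov] / dd * step), idvec)
      ids <- as.integer(rownames(axm))
      aym <- rowsum(c(dy[ov] / dd * step, -dy[ov] / dd * step), idvec)
      x[ids] <- (x[ids] + axm[, 1] + rnorm(length(ids), 0, 0.01)) %% L
      y[ids] <- (y[ids] + aym[, 1] + rnorm(length(ids), 0, 0.01)) %% L
      scount <- scount + 1L
      if (scount >= 40L) rebuild <- TRUE
    }
    if (scale >= 1 && done) break
    if (!done)
      stop(sprintf("packing stage at scale %.3f did not converge", scale))
    scale <- min(1, scale * if (scale > 0.92) 1.015 else 1.05)
  }
  list(x = x, y = y, r = r_full)
}
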