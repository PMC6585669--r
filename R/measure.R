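#' Measure a label map
#'
#' Computes compartment volume fractions (summing to 1), the fiber area
#' fraction (intra + myelin) and, when the map carries an `axon_id` raster,
#' per-fiber pixel-count areas, g-ratios and effective radii
#' (`sqrt(area / pi)`).
#'
#' @param map A [label_map()].
#' @param axons Optional [axon_set()] used to attach analytic values next to
#'   the raster measurements (defaults to the set stored in the map).
#' @return A `wm_measurements` list with elements `fractions` (named numeric:
#'   extra, intra, myelin), `fiber_area_fraction`, `n_axons` and `per_axon`
#'   (tibble, possibly empty). Use [tidy()] for a tabular view.
#' @export
measure <- function(map, axons = NULL) {
  stopifnot(inherits(map, "label_map"))
  axons <- axons %||% map$axons
  fr <- compartment_fractions(map)
  per <- tibble::tibble()
  if (!is.null(map$axon_id)) {
    n_ax <- max(map$axon_id)
    if (n_ax > 0) {
      px_area <- map$grid$pixel_size^2
      lin_in <- map$axon_id[map$labels == LBL_INTRA]
      lin_my <- map$axon_id[map$labels == LBL_MYELIN]
      ci <- tabulate(lin_in, nbins = n_ax)
      cm <- tabulate(lin_my, nbins = n_ax)
      A_i <- ci * px_area; A_t <- (ci + cm) * px_area
      per <- tibble::tibble(
        id = seq_len(n_ax), A_i = A_i, A_t = A_t,
        g = ifelse(A_t > 0, sqrt(A_i / A_t), NA_real_),
        r_eff = sqrt(A_i / pi))
      if (!is.null(axons))
        per <- dplyr::left_join(
          per,
          tibble::tibble(id = axons$id, g_analytic = axons$g,
                         A_t_analytic = axons$A_t),
          by = "id")
    }
  }
  structure(list(fractions = fr,
                 fiber_area_fraction = unname(fr["intra"] + fr["myelin"]),
                 n_axons = if (nrow(per)) nrow(per) else NA_integer_,
                 per_axon = per),
            class = "wm_measurements")
}

#' @export
print.wm_measurements <- function(x, ...) {
  cat(sprintf(
    "<wm_measurements> extra %.3f / intra %.3f / myelin %.3f (fiber %.3f)\n",
    x$fractions["extra"], x$fractions["intra"], x$fractions["myelin"],
    x$fiber_area_fraction))
  if (nrow(x$per_axon))
    cat(sprintf("  %d fibers, median raster g = %.3f\n", nrow(x$per_axon),
                stats::median(x$per_axon$g, na.rm = TRUE)))
  invisible(x)
}

#' @method tidy wm_measurements
#' @export
tidy.wm_measurements <- function(x, ...) x$per_axon

#' @method glance wm_measurements
#' @export
glance.wm_measurements <- function(x, ...) {
  tibble::tibble(extra_fraction = unname(x$fractions["extra"]),
                 intra_fraction = unname(x$fractions["intra"]),
                 myelin_fraction = unname(x$fractions["myelin"]),
                 fiber_area_fraction = x$fiber_area_fraction,
                 n_axons = x$n_axons)
}
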