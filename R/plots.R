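# ggplot2 methods for the main result types.

#' @method autoplot wm_signal
#' @export
autoplot.wm_signal <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("magnitude", "phase_rad"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(magnitude = "normalized magnitude",
                            phase_rad = "unwrapped phase (rad)"))) +
    ggplot2::labs(x = "echo time (ms)", y = NULL)
}

#' @method autoplot wm_histogram
#' @export
autoplot.wm_histogram <- function(object, ...) {
  df <- object$bins |>
    tidyr::pivot_longer(c("extra", "intra", "myelin", "total"),
                        names_to = "compartment", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$count,
                                   color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "off-resonance frequency (Hz)", y = "pixel count")
}

#' @method autoplot field_map
#' @export
autoplot.field_map <- function(object, downsample = NULL, ...) {
  n <- object$grid$n
  ds <- downsample %||% max(1L, floor(n / 512))
  idx <- seq(1L, n, by = ds)
  xs <- grid_centers(object$grid)[idx]
  df <- expand.grid(x = xs, y = xs)
  df$delta_f <- as.vector(object$delta_f[idx, idx])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$delta_f)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black",
                                  high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "Hz")
}

#' @method autoplot label_map
#' @export
autoplot.label_map <- function(object, downsample = NULL, ...) {
  n <- object$grid$n
  ds <- downsample %||% max(1L, floor(n / 512))
  idx <- seq(1L, n, by = ds)
  xs <- grid_centers(object$grid)[idx]
  df <- expand.grid(x = xs, y = xs)
  df$compartment <- factor(c("extra", "intra", "myelin")[
    as.vector(object$labels[idx, idx]) + 1L],
    levels = c("extra", "intra", "myelin"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(extra = "black", intra = "gray60",
                                          myelin = "white")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' @method autoplot wm_sweep
#' @export
autoplot.wm_sweep <- function(object, ...) {
  df <- object$signals |>
    tidyr::pivot_longer(c("magnitude", "phase_rad"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   color = .data$run,
                                   linetype = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "echo time (ms)", y = NULL)
}

#' @importFrom ggplot2 .data
NULL
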