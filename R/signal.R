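#' Static three-compartment GRE signal
#'
#' Computes the complex signal under static magnetization,
#' `S(t) = sum_n rho_n exp(-t / T2_n) sum_{pixels in n within mask}
#' exp(i s 2 pi df t)`, with `s = sign_convention`. The magnitude is
#' normalized to `|S(0)| = sum_n rho_n area_n` and the phase is temporally
#' unwrapped. The default sign (+1) makes a positive mean frequency produce
#' positive phase accrual.
#'
#' For very large masks the per-compartment frequency values are compressed
#' onto a fine frequency grid before the echo loop (`freq_bin`, Hz); the
#' worst-case phase error per pixel is `pi * freq_bin * t_max / 1000`, about
#' 9e-4 rad for the default 0.01 Hz at 55 ms. Set `freq_bin = 0` to force the
#' exact sum (the automatic default for maps up to about a megapixel).
#'
#' @param field A `field_map`.
#' @param map The matching [label_map()].
#' @param props [compartment_properties()].
#' @param echoes Echo times in ms (see [echo_times()]).
#' @param mask A [sample_mask()]; defaults to the 50%-area central disk.
#' @param sign_convention +1 or -1 phase sign.
#' @param freq_bin Frequency compression bin in Hz, 0 for exact, NULL for
#'   automatic.
#' @return A `wm_signal`: tibble of `time_ms`, `magnitude`, `phase_rad`
#'   (unwrapped), `real`, `imag`, plus metadata attributes.
#' @export
static_signal <- function(field, map, props = compartment_properties(),
                          echoes = echo_times("static"), mask = NULL,
                          sign_convention = 1, freq_bin = NULL) {
  stopifnot(inherits(field, "field_map"), inherits(map, "label_map"),
            sign_convention %in% c(-1, 1))
  check_same_grid(field$grid, map$grid)
  mask <- mask %||% sample_mask(field$grid)
  check_same_grid(field$grid, mask$grid)
  if (!any(mask$mask)) stop("empty sample mask")
  sel <- mask$mask
  f_all <- field$delta_f[sel]
  lb_all <- map$labels[sel]
  if (is.null(freq_bin)) freq_bin <- if (length(f_all) > 2^20) 0.01 else 0
  S <- complex(real = numeric(length(echoes)),
               imaginary = numeric(length(echoes)))
  S0 <- 0
  for (cm in c(LBL_EXTRA, LBL_INTRA, LBL_MYELIN)) {
    comp <- c("extra", "intra", "myelin")[cm + 1L]
    pr <- props_row(props, comp)
    f <- f_all[lb_all == cm]
    if (!length(f)) next
    if (freq_bin > 0) {
      tb <- table(round(f / freq_bin))
      fv <- as.numeric(names(tb)) * freq_bin
      wv <- as.numeric(tb)
    } else {
      fv <- f; wv <- rep(1, length(f))
    }
    S0 <- S0 + pr$rho * length(f)
    env <- pr$rho * exp(-echoes / pr$T2_ms)
    ang <- sign_convention * 2 * pi * fv / 1000
    for (k in seq_along(echoes))
      S[k] <- S[k] + env[k] * sum(wv * exp(1i * ang * echoes[k]))
  }
  new_wm_signal(echoes, S / S0,
                meta = list(kind = "static", sign = sign_convention,
                            mask_fraction = mask$fraction,
                            freq_bin = freq_bin))
}

# Construct the signal tibble with normalized magnitude and unwrapped phase.
new_wm_signal <- function(times, S, meta = list()) {
  phase <- unwrap_phase_series(S)
  out <- tibble::tibble(time_ms = times, magnitude = Mod(S),
                        phase_rad = phase, real = Re(S), imag = Im(S))
  structure(out, meta = meta, class = c("wm_signal", class(out)))
}

#' Temporally unwrap the phase of a complex series
#'
#' Takes the argument of each sample and adds multiples of 2 pi so adjacent
#' samples never jump by more than pi; the first sample lies in (-pi, pi].
#' Samples with (numerically) zero magnitude have undefined phase; their
#' increments are interpolated from the neighboring samples and a message is
#' emitted (the packed circular model's beat null produces exactly this).
#'
#' @param z Complex vector, sampled densely enough that true phase steps stay
#'   below pi.
#' @return Numeric vector of unwrapped phase, radians.
#' @export
unwrap_phase_series <- function(z) {
  stopifnot(is.complex(z) || is.numeric(z))
  z <- as.complex(z)
  n <- length(z)
  if (n == 0) return(numeric(0))
  tol <- max(Mod(z)) * 1e-12
  dead <- Mod(z) <= tol
  ph <- Arg(z)
  if (any(dead)) {
    message(sum(dead), " zero-magnitude sample(s); phase interpolated")
    alive <- which(!dead)
    if (length(alive) >= 2)
      ph[dead] <- approx(alive, ph[alive], xout = which(dead),
                         rule = 2)$y
  }
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}

#' @export
print.wm_signal <- function(x, ...) {
  meta <- attr(x, "meta")
  last <- nrow(x)
  cat(sprintf(
    "<wm_signal> %s, %d echoes to %.3g ms; magnitude %.3f, phase %.3f rad at last echo\n",
    meta$kind %||% "?", last, x$time_ms[last], x$magnitude[last],
    x$phase_rad[last]))
  invisible(x)
}

#' @method tidy wm_signal
#' @export
tidy.wm_signal <- function(x, ...) tibble::as_tibble(x)

#' @method glance wm_signal
#' @export
glance.wm_signal <- function(x, ...) {
  last <- nrow(x)
  tibble::tibble(n_echoes = last, t_max_ms = x$time_ms[last],
                 magnitude_final = x$magnitude[last],
                 phase_final_rad = x$phase_rad[last],
                 abs_phase_final_rad = abs(x$phase_rad[last]))
}

# Signal value at (or interpolated to) a given echo time.
signal_at <- function(sig, t_ms) {
  c(magnitude = approx(sig$time_ms, sig$magnitude, t_ms)$y,
    phase_rad = approx(sig$time_ms, sig$phase_rad, t_ms)$y)
}

#' Write a signal series with run metadata to CSV
#'
#' Metadata (geometry hash, susceptibilities, orientation, field strength,
#' seeds) goes into `# key: value` header lines followed by the standard
#' columns.
#'
#' @param x A `wm_signal`.
#' @param path Output path.
#' @param metadata Named list written into the header.
#' @export
write_signal_csv <- function(x, path, metadata = list()) {
  meta <- c(attr(x, "meta"), metadata)
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
    character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tibble::as_tibble(x), con, row.names = FALSE)
  invisible(path)
}
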