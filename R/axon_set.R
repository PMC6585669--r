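#' Axon cross-section sets
#'
#' An `axon_set` is a tibble with one row per myelinated fiber and columns
#' `id`, `x`, `y` (center, um), `r_outer`, `r_inner` (um; `NA` for
#' free-form outlines), list-columns `outer` and `inner` holding boundary
#' polygons (k x 2 vertex matrices, um; `NULL` for analytic circles),
#' `A_i`, `A_t` (intra-axonal and total fiber areas, um^2), `g`
#' (= sqrt(A_i/A_t)) and `kind` (`"circle"` or `"polygon"`). The physical
#' domain and boundary convention travel as attributes: `extent` (um) and
#' `periodic` (fibers live on a torus, the convention used by the packed
#' geometries so that the raster matches the spectral field solver's implicit
#' periodicity).
#'
#' @param axons A data frame with at least the geometric columns above.
#' @param extent Physical domain side length, um.
#' @param periodic Whether fibers wrap across the domain boundary.
#' @return The validated `axon_set` tibble.
#' @export
axon_set <- function(axons, extent, periodic = FALSE) {
  ax <- tibble::as_tibble(axons)
  stopifnot(all(c("id", "x", "y", "kind") %in% names(ax)))
  if (!"outer" %in% names(ax)) ax$outer <- vector("list", nrow(ax))
  if (!"inner" %in% names(ax)) ax$inner <- vector("list", nrow(ax))
  if (!"r_outer" %in% names(ax)) ax$r_outer <- NA_real_
  if (!"r_inner" %in% names(ax)) ax$r_inner <- NA_real_
  ax <- recompute_axon_measures(ax)
  bad <- which(!(ax$g > 0 & ax$g < 1))
  if (length(bad))
    stop("invalid g-ratio for axon(s) ", paste(head(bad, 5), collapse = ", "))
  structure(ax, extent = as.numeric(extent), periodic = isTRUE(periodic),
            class = c("axon_set", class(tibble::tibble())))
}

# A_i, A_t and g from radii (circles) or boundary polygons.
recompute_axon_measures <- function(ax) {
  circ <- ax$kind == "circle"
  A_i <- numeric(nrow(ax)); A_t <- numeric(nrow(ax))
  A_i[circ] <- pi * ax$r_inner[circ]^2
  A_t[circ] <- pi * ax$r_outer[circ]^2
  for (k in which(!circ)) {
    A_i[k] <- polygon_area(ax$inner[[k]])
    A_t[k] <- polygon_area(ax$outer[[k]])
  }
  ax$A_i <- A_i; ax$A_t <- A_t
  ax$g <- sqrt(A_i / A_t)
  ax
}

axon_extent <- function(ax) attr(ax, "extent")
axon_periodic <- function(ax) isTRUE(attr(ax, "periodic"))

#' @export
print.axon_set <- function(x, ...) {
  cat(sprintf(
    "<axon_set> %d fibers on %.3g um domain (%s); mean g = %.3f, fiber area fraction = %.3f\n",
    nrow(x), axon_extent(x), if (axon_periodic(x)) "periodic" else "bounded",
    mean(x$g), sum(x$A_t) / axon_extent(x)^2))
  NextMethod()
}

# Boundary polygons for any axon, generating them on demand for circles.
axon_polygons <- function(ax, k, n_vertices = 96) {
  if (ax$kind[k] == "circle") {
    list(outer = circle_polygon(ax$x[k], ax$y[k], ax$r_outer[k], n_vertices),
         inner = circle_polygon(ax$x[k], ax$y[k], ax$r_inner[k], n_vertices))
  } else {
    list(outer = ax$outer[[k]], inner = ax$inner[[k]])
  }
}

# Convert every circular axon to an explicit polygon pair (needed before any
# free-form transform such as warping).
as_polygon_axons <- function(ax, n_vertices = 96) {
  for (k in which(ax$kind == "circle")) {
    p <- axon_polygons(ax, k, n_vertices)
    ax$outer[[k]] <- p$outer
    ax$inner[[k]] <- p$inner
    ax$kind[k] <- "polygon"
  }
  recompute_axon_measures(ax)
}

#' Serialize an axon set to newline-delimited JSON
#'
#' One JSON record per line per axon (id, center, radii, vertex lists, areas,
#' g), preceded by a header line with the domain metadata. Lossless for
#' round-tripping.
#'
#' @param ax An [axon_set()].
#' @param path Output file path.
#' @export
write_axon_set <- function(ax, path) {
  header <- jsonlite::toJSON(list(format = "wmgre_axon_set", version = 1L,
                                  extent = axon_extent(ax),
                                  periodic = axon_periodic(ax)),
                             auto_unbox = TRUE, digits = NA)
  recs <- vapply(seq_len(nrow(ax)), function(k) {
    jsonlite::toJSON(list(
      id = ax$id[k], x = ax$x[k], y = ax$y[k],
      r_outer = ax$r_outer[k], r_inner = ax$r_inner[k],
      kind = ax$kind[k],
      outer = if (is.null(ax$outer[[k]])) NULL else unclass(ax$outer[[k]]),
      inner = if (is.null(ax$inner[[k]])) NULL else unclass(ax$inner[[k]]),
      A_i = ax$A_i[k], A_t = ax$A_t[k], g = ax$g[k]),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read an axon set written by [write_axon_set()]
#' @param path File path.
#' @return An [axon_set()].
#' @export
read_axon_set <- function(path) {
  lines <- readLines(path)
  hd <- jsonlite::fromJSON(lines[1])
  if (!identical(hd$format, "wmgre_axon_set")) stop("not an axon-set file")
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  ax <- tibble::tibble(
    id = vapply(recs, function(r) as.integer(r$id), integer(1)),
    x = vapply(recs, function(r) r$x, numeric(1)),
    y = vapply(recs, function(r) r$y, numeric(1)),
    r_outer = vapply(recs, function(r) r$r_outer %||% NA_real_, numeric(1)),
    r_inner = vapply(recs, function(r) r$r_inner %||% NA_real_, numeric(1)),
    outer = lapply(recs, function(r) if (is.null(r$outer)) NULL else
      matrix(as.numeric(r$outer), ncol = 2)),
    inner = lapply(recs, function(r) if (is.null(r$inner)) NULL else
      matrix(as.numeric(r$inner), ncol = 2)),
    kind = vapply(recs, function(r) r$kind, character(1))
  )
  axon_set(ax, extent = hd$extent, periodic = hd$periodic)
}
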