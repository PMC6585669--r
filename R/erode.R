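#' Erode myelin from the inside out (demyelination)
#'
#' Thins the myelin sheath by moving each fiber's inner boundary outward
#' while the outer boundary stays fixed: the removed innermost myelin is
#' reassigned to intra-axonal water, so `A_t` (and hence the fiber density)
#' is unchanged while `g = sqrt(A_i / A_t)` rises to `target_g`. This models
#' demyelination sweeps with g from 0.70 (healthy) to 0.98 (severe loss).
#'
#' For circular fibers the new inner radius is `target_g * r_outer` exactly;
#' for polygonal fibers the inner boundary is rescaled about its centroid to
#' the required area; for raster maps the innermost myelin pixel layers
#' (ordered by distance to the fiber's intra-axonal region) are relabeled
#' until the pixel-measured g is within one layer quantum of the target.
#'
#' @param x An [axon_set()] or [label_map()] (the latter must carry an
#'   `axon_id` raster, i.e. come from [rasterize()]).
#' @param target_g Target g-ratio; must not be below any fiber's current g
#'   (myelin is never regrown).
#' @return Object of the same type as `x`.
#' @export
erode_myelin <- function(x, target_g) {
  UseMethod("erode_myelin")
}

#' @export
erode_myelin.axon_set <- function(x, target_g) {
  stopifnot(target_g > 0, target_g < 1)
  if (any(x$g > target_g + 1e-9))
    stop(sprintf("target_g = %.3f is below the current g of %d fiber(s); %s",
                 target_g, sum(x$g > target_g + 1e-9),
                 "remyelination is not modeled"))
  circ <- x$kind == "circle"
  x$r_inner[circ] <- target_g * x$r_outer[circ]
  for (k in which(!circ)) {
    f <- sqrt(target_g^2 * x$A_t[k] / x$A_i[k])
    ctr <- polygon_centroid(x$inner[[k]])
    p <- x$inner[[k]]
    p[, 1] <- ctr[1] + (p[, 1] - ctr[1]) * f
    p[, 2] <- ctr[2] + (p[, 2] - ctr[2]) * f
    if (any(!points_in_polygon(p[, 1], p[, 2], x$outer[[k]])))
      stop("eroded inner boundary of axon ", x$id[k],
           " would cross its outer boundary")
    x$inner[[k]] <- p
  }
  axon_set(recompute_axon_measures(x), extent = axon_extent(x),
           periodic = axon_periodic(x))
}

#' @export
erode_myelin.label_map <- function(x, target_g) {
  stopifnot(target_g > 0, target_g < 1)
  if (is.null(x$axon_id))
    stop("raster erosion needs the axon_id raster produced by rasterize()")
  lab <- x$labels; ids <- x$axon_id
  n_ax <- max(ids)
  lin_my <- which(lab == LBL_MYELIN)
  lin_in <- which(lab == LBL_INTRA)
  n_px <- nrow(lab)
  for (a in seq_len(n_ax)) {
    my_a <- lin_my[ids[lin_my] == a]
    in_a <- lin_in[ids[lin_in] == a]
    A_t <- length(my_a) + length(in_a)
    if (A_t == 0L) next
    g_cur <- sqrt(length(in_a) / A_t)
    if (g_cur > target_g + 1e-9)
      stop(sprintf("axon %d has measured g = %.3f above target %.3f", a,
                   g_cur, target_g))
    need <- round(target_g^2 * A_t) - length(in_a)
    if (need <= 0L) next
    d <- ring_distance_to_intra(lab, ids, my_a, in_a, n_px, a, x$periodic)
    ord <- order(d, my_a)
    flip <- my_a[ord][seq_len(min(need, length(my_a)))]
    lab[flip] <- LBL_INTRA
  }
  out <- label_map(lab, x$grid, axon_id = ids, axons = x$axons,
                   periodic = x$periodic)
  out
}

# BFS ring index of each myelin pixel of one axon, measured from its
# intra-axonal region (4-connectivity, wrap-aware when periodic).
ring_distance_to_intra <- function(lab, ids, my_a, in_a, n_px, a, periodic) {
  d <- rep(Inf, length(my_a))
  remaining <- rep(TRUE, length(my_a))
  frontier <- in_a
  o <- order(my_a); sorted <- my_a[o]
  ring <- 0L
  while (length(frontier) && any(remaining)) {
    ring <- ring + 1L
    nb <- neighbors4(frontier, n_px, periodic)
    nb <- unique(nb[nb > 0L])
    hit <- nb[!is.na(fastmatch_sorted(nb, sorted))]
    hitpos <- o[fastmatch_sorted(hit, sorted)]
    newly <- hitpos[remaining[hitpos] ]
    if (!length(newly)) break
    d[newly] <- ring
    remaining[newly] <- FALSE
    frontier <- my_a[newly]
  }
  d[remaining] <- ring + 1L
  d
}

# 4-neighborhood of linear indices in an n x n matrix; 0 for off-grid
# (non-periodic) neighbors.
neighbors4 <- function(lin, n, periodic) {
  i <- ((lin - 1L) %% n) + 1L
  j <- ((lin - 1L) %/% n) + 1L
  if (periodic) {
    im <- ifelse(i == 1L, n, i - 1L); ip <- ifelse(i == n, 1L, i + 1L)
    jm <- ifelse(j == 1L, n, j - 1L); jp <- ifelse(j == n, 1L, j + 1L)
    c((jm - 1L) * n + i, (jp - 1L) * n + i,
      (j - 1L) * n + im, (j - 1L) * n + ip)
  } else {
    res <- c(ifelse(j > 1L, (j - 2L) * n + i, 0L),
             ifelse(j < n, j * n + i, 0L),
             ifelse(i > 1L, (j - 1L) * n + i - 1L, 0L),
             ifelse(i < n, (j - 1L) * n + i + 1L, 0L))
    res
  }
}

# match() against a sorted integer vector via findInterval (fast path).
fastmatch_sorted <- function(x, sorted) {
  pos <- findInterval(x, sorted)
  ok <- pos > 0L & sorted[pmax(pos, 1L)] == x
  ifelse(ok, pos, NA_integer_)
}
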