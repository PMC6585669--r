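# Planar polygon helpers. Polygons are k x 2 matrices of (x, y) vertices in
# micrometers, implicitly closed (last vertex connects to the first).

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_perimeter <- function(p) {
  dx <- diff(c(p[, 1], p[1, 1]))
  dy <- diff(c(p[, 2], p[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

# 4*pi*A/P^2: 1 for a circle, < 1 for anything else.
polygon_circularity <- function(p) {
  4 * pi * polygon_area(p) / polygon_perimeter(p)^2
}

polygon_centroid <- function(p) c(mean(p[, 1]), mean(p[, 2]))

# Vectorized even-odd (crossing number) point-in-polygon test.
# px, py: coordinates of query points; poly: k x 2 vertex matrix.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

# Regular-polygon approximation of a circle (used when converting circular
# axons to explicit boundary curves).
circle_polygon <- function(cx, cy, r, n_vertices = 96) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_polygon <- function(cx, cy, a, b, rotation = 0, n_vertices = 256) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cr <- cos(rotation); sr <- sin(rotation)
  cbind(cx + x * cr - y * sr, cy + x * sr + y * cr)
}

polygon_is_closed_simple <- function(p) {
  is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3 && all(is.finite(p))
}
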