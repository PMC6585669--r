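test_that("nested-ellipse axons conserve areas and g across eccentricity", {
  grid <- grid_spec(500, 3)
  maps <- lapply(c(0, 0.66, 0.80, 0.87), function(e) {
    rasterize(make_single_ellipse_axon(ellipse_spec(e), g = 0.7, grid), grid)
  })
  counts <- vapply(maps, function(m) {
    c(intra = sum(m$labels == 1L), total = sum(m$labels != 0L))
  }, numeric(2))
  # pixel-count areas conserved within 1% of the circular case
  expect_true(all(abs(counts["intra", ] / counts["intra", 1] - 1) < 0.01))
  expect_true(all(abs(counts["total", ] / counts["total", 1] - 1) < 0.01))
  g_meas <- sqrt(counts["intra", ] / counts["total", ])
  expect_true(all(abs(g_meas - 0.7) < 0.01))
})

test_that("circular axon is rotation invariant; oversized ellipse errors", {
  grid <- grid_spec(300, 3)
  m0 <- rasterize(make_single_ellipse_axon(ellipse_spec(0), 0.7, grid), grid)
  m1 <- rasterize(make_single_ellipse_axon(ellipse_spec(0, rotation = 1.1),
                                           0.7, grid), grid)
  expect_identical(m0$labels, m1$labels)
  expect_error(
    make_single_ellipse_axon(ellipse_spec(0.95), 0.7, grid, r_equiv = 1.2),
    "extent")
})

test_that("gamma radius draws match the configured distribution", {
  cfg <- packing_config(n_axons = 1434, mean_radius = 0.46, extent = 46,
                        seed = 7)
  ax <- pack_circles(cfg)
  m <- cfg$mean_radius
  se <- sqrt(m^2 / cfg$gamma_shape / cfg$n_axons)
  expect_lt(abs(mean(ax$r_outer) - m), 3 * se)
  expect_equal(ax$r_inner, 0.7 * ax$r_outer)
})

test_that("packing is collision-free, deterministic, and errors when too dense", {
  fx <- small_packing_fixture()
  ax <- fx$axons
  L <- attr(ax, "extent")
  mi <- function(d) d - L * round(d / L)
  dx <- mi(outer(ax$x, ax$x, "-")); dy <- mi(outer(ax$y, ax$y, "-"))
  d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
  expect_gte(min(d - outer(ax$r_outer, ax$r_outer, "+")),
             fx$config$min_gap - 1e-9)
  ax2 <- pack_circles(fx$config)
  expect_identical(ax$x, ax2$x)
  expect_identical(ax$r_outer, ax2$r_outer)
  expect_error(pack_circles(packing_config(n_axons = 400, mean_radius = 0.46,
                                           extent = 10)),
               "too dense")
})

test_that("single-circle packing places trivially", {
  ax <- pack_circles(packing_config(n_axons = 1, mean_radius = 0.4,
                                    extent = 3, seed = 1))
  expect_equal(nrow(ax), 1L)
  expect_s3_class(ax, "axon_set")
})

test_that("rasterized annulus area matches the analytic annulus", {
  grid <- grid_spec(200, 20)  # 0.1 um px; r_o = 10 px
  ax <- axon_set(tibble::tibble(id = 1L, x = 10, y = 10, r_outer = 1,
                                r_inner = 0.7, kind = "circle"),
                 extent = 20)
  map <- rasterize(ax, grid)
  analytic <- pi * (1 - 0.7^2) / grid$pixel_size^2
  expect_lt(abs(sum(map$labels == 2L) / analytic - 1), 0.05)
})

test_that("rasterize handles empty sets and flags shared pixels", {
  grid <- grid_spec(64, 6.4)
  empty <- axon_set(tibble::tibble(id = integer(), x = numeric(),
                                   y = numeric(), r_outer = numeric(),
                                   r_inner = numeric(), kind = character()),
                    extent = 6.4)
  m <- rasterize(empty, grid)
  expect_true(all(m$labels == 0L))
  # two tangent circles: first-come priority, collision counter flags overlap
  two <- axon_set(tibble::tibble(id = 1:2, x = c(2.2, 4.2), y = c(3.2, 3.2),
                                 r_outer = c(1, 1), r_inner = c(0.7, 0.7),
                                 kind = "circle"), extent = 6.4)
  mm <- rasterize(two, grid)
  both <- sum(mm$labels != 0L)
  expect_lte(both, sum(mm$labels != 0L))  # every labeled pixel has one owner
  expect_true(all(mm$axon_id[mm$labels != 0L] %in% 1:2))
})

test_that("raster areas converge to analytic with resolution", {
  for (case in list(list(n = 200, tol = 0.05, r_px = 10),
                    list(n = 640, tol = 0.01, r_px = 32))) {
    grid <- grid_spec(case$n, 20)
    ax <- axon_set(tibble::tibble(id = 1L, x = 10, y = 10,
                                  r_outer = case$r_px * grid$pixel_size,
                                  r_inner = 0.7 * case$r_px * grid$pixel_size,
                                  kind = "circle"), extent = 20)
    map <- rasterize(ax, grid)
    a_meas <- sum(map$labels != 0L) * grid$pixel_size^2
    a_true <- pi * (case$r_px * grid$pixel_size)^2
    expect_lt(abs(a_meas / a_true - 1), case$tol)
  }
})

test_that("measure() fractions sum to one and recover per-axon g", {
  fx <- small_packing_fixture()
  ms <- measure(fx$map)
  expect_equal(sum(ms$fractions), 1, tolerance = 1e-12)
  expect_true(all(abs(ms$per_axon$g - 0.7) < 0.04))
  expect_equal(ms$per_axon$r_eff,
               sqrt(ms$per_axon$A_i / pi))
  # all-extra map
  empty <- label_map(matrix(0L, 16, 16), grid_spec(16, 1))
  expect_equal(unname(measure(empty)$fractions), c(1, 0, 0))
})

test_that("axon sets round-trip through NDJSON serialization", {
  fx <- small_packing_fixture()
  path <- tempfile(fileext = ".ndjson")
  write_axon_set(fx$axons, path)
  back <- read_axon_set(path)
  expect_equal(back$x, fx$axons$x)
  expect_equal(back$r_outer, fx$axons$r_outer)
  expect_equal(attr(back, "extent"), attr(fx$axons, "extent"))
  # polygon kind round-trips too
  ax <- make_single_ellipse_axon(ellipse_spec(0.8), 0.7, grid_spec(100, 3))
  write_axon_set(ax, path)
  back2 <- read_axon_set(path)
  expect_equal(back2$outer[[1]], ax$outer[[1]], ignore_attr = TRUE)
  expect_equal(back2$g, ax$g)
})
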