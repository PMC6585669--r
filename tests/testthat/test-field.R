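test_that("tensor map follows the hollow-cylinder convention", {
  fx <- single_axon_fixture()
  orient <- orientation_map(fx$map)
  chi <- build_tensor_map(fx$map, orient)
  # pixel due east of the centroid: phi = 0, lab tensor diag(-180, 0, 0)
  ctr_px <- round(3 / fx$grid$pixel_size)
  east <- ctr_px + round(0.45 / fx$grid$pixel_size)  # mid-myelin
  expect_equal(fx$map$labels[east, ctr_px], 2L)
  phi_e <- orient$phi[east, ctr_px]
  expect_lt(min(phi_e, 2 * pi - phi_e), 0.02)
  expect_equal(chi$xx[east, ctr_px], -180, tolerance = 0.05)
  expect_equal(chi$yy[east, ctr_px], 0, tolerance = 0.5)
  expect_equal(chi$zz[east, ctr_px], 0)
  # trace is rotation invariant: 3 chi_i = -180 on every myelin pixel
  my <- fx$map$labels == 2L
  tr <- chi$xx[my] + chi$yy[my] + chi$zz[my]
  expect_true(all(abs(tr + 180) < 1e-9))
  # chi_a = 0 collapses to chi_i * identity everywhere on myelin
  chi0 <- build_tensor_map(fx$map, orient,
                           compartment_properties(chi_aniso = 0))
  expect_true(all(abs(chi0$xx[my] + 60) < 1e-9))
  expect_true(all(abs(chi0$xy[my]) < 1e-9))
})

test_that("forward field reproduces the analytic hollow-cylinder shift", {
  fx <- single_axon_fixture()
  fld <- single_axon_field()
  intra <- fld$delta_f[fx$map$labels == 1L]
  target <- analytic_hollow_cylinder(0.7)
  expect_equal(target, -9.568, tolerance = 1e-4)
  expect_lt(abs(mean(intra) / target - 1), 0.03)
  # grid mean is zero (DC bin convention)
  expect_lt(abs(mean(fld$delta_f)), 1e-9)
})

test_that("parallel fiber produces zero aqueous field", {
  fx <- single_axon_fixture()
  orient <- orientation_map(fx$map)
  chi <- build_tensor_map(fx$map, orient)
  fld <- forward_field(chi, field_config(theta = 0))
  aq <- fx$map$labels != 2L
  # the bracket reduces to a pointwise chi_zz/3 term supported on myelin;
  # aqueous pixels only see the (tiny) effect of DC-bin zeroing
  dc <- mean(chi$zz) / 3 * 1e-9 * field_config()$f0_hz
  expect_lt(max(abs(fld$delta_f[aq] + dc)), 0.02)
  expect_equal(analytic_hollow_cylinder(0.7, cfg = field_config(theta = 0)),
               0)
})

test_that("zero tensor gives an identically zero field", {
  grid <- grid_spec(32, 2)
  chi <- structure(list(grid = grid, xx = matrix(0, 32, 32),
                        yy = matrix(0, 32, 32), zz = matrix(0, 32, 32),
                        xy = matrix(0, 32, 32), xz = NULL, yz = NULL,
                        periodic = TRUE), class = "tensor_field")
  expect_true(all(forward_field(chi)$delta_f == 0))
  expect_true(all(direct_convolution_oracle(chi)$delta_f == 0))
})

test_that("FFT solver matches the brute-force spectral oracle", {
  # single-pixel source, anisotropic tensor with off-diagonal terms
  grid <- grid_spec(64, 4)
  z <- matrix(0, 64, 64)
  xx <- z; yy <- z; zz <- z; xy <- z
  xx[20, 31] <- -180; yy[20, 31] <- -30; zz[20, 31] <- -60; xy[20, 31] <- 25
  chi <- structure(list(grid = grid, xx = xx, yy = yy, zz = zz, xy = xy,
                        xz = NULL, yz = NULL, periodic = TRUE),
                   class = "tensor_field")
  cfg <- field_config(theta = 1.1)
  a <- forward_field(chi, cfg)$delta_f
  b <- direct_convolution_oracle(chi, cfg)$delta_f
  expect_lt(max(abs(a - b)), 1e-6 * max(abs(a)))
  # two-pixel source: linearity of the operator
  xx2 <- z; xx2[40, 10] <- -90
  chi2 <- chi; chi2$xx <- xx2; chi2$yy <- z; chi2$zz <- z; chi2$xy <- z
  chi12 <- chi; chi12$xx <- xx + xx2
  f1 <- forward_field(chi, cfg)$delta_f
  f2 <- forward_field(chi2, cfg)$delta_f
  f12 <- forward_field(chi12, cfg)$delta_f
  expect_lt(max(abs(f12 - f1 - f2)), 1e-10 * max(abs(f12)))
  expect_error(direct_convolution_oracle(
    structure(list(grid = grid_spec(256, 4)), class = "tensor_field")),
    "128")
})

test_that("field solver is linear in the tensor amplitude", {
  fx <- single_axon_fixture()
  orient <- orientation_map(fx$map)
  chi <- build_tensor_map(fx$map, orient)
  chi3 <- chi
  for (cc in c("xx", "yy", "zz", "xy")) chi3[[cc]] <- 3 * chi[[cc]]
  f1 <- forward_field(chi)$delta_f
  f3 <- forward_field(chi3)$delta_f
  expect_lt(max(abs(f3 - 3 * f1)), 1e-10 * max(abs(f3)))
})

test_that("compartment histograms report modal peaks per compartment", {
  fx <- single_axon_fixture()
  fld <- single_axon_field()
  h <- compartment_histograms(fld, fx$map, sample_mask(fx$grid, 0.5))
  pk <- h$peaks
  expect_equal(pk$peak_hz[pk$compartment == "extra"], 0, tolerance = 0.5)
  expect_equal(pk$peak_hz[pk$compartment == "intra"], -9.6, tolerance = 0.5)
  expect_equal(sum(h$bins$total), sum(h$bins$extra + h$bins$intra +
                                        h$bins$myelin))
  expect_equal(sum(h$bins$total), sum(sample_mask(fx$grid, 0.5)$mask))
  # uniform zero field: all mass in the bin containing zero
  zf <- field_map(matrix(0, fx$grid$n, fx$grid$n), fx$grid)
  hz <- compartment_histograms(zf, fx$map)
  expect_true(all(abs(hz$peaks$peak_hz) <= 0.25))
  # an empty compartment yields an NA peak
  allex <- label_map(matrix(0L, fx$grid$n, fx$grid$n), fx$grid)
  h2 <- compartment_histograms(zf, allex)
  expect_true(is.na(h2$peaks$peak_hz[h2$peaks$compartment == "myelin"]))
})

test_that("variant susceptibility shifts the intra peak as expected", {
  fx <- single_axon_fixture()
  orient <- orientation_map(fx$map)
  chi <- build_tensor_map(fx$map, orient,
                          compartment_properties(chi_aniso = -70))
  fld <- forward_field(chi)
  intra <- fld$delta_f[fx$map$labels == 1L]
  expect_lt(abs(mean(intra) - analytic_hollow_cylinder(0.7, -70)), 0.2)
  expect_equal(analytic_hollow_cylinder(0.7, -70), -5.58, tolerance = 0.002)
})

test_that("uniform offsets compose additively", {
  fld <- single_axon_field()
  a <- apply_uniform_offset(fld, 1.5)
  b <- apply_uniform_offset(a, -0.5)
  ab <- apply_uniform_offset(fld, 1.0)
  expect_equal(b$delta_f, ab$delta_f)
  expect_equal(apply_uniform_offset(fld, 0)$delta_f, fld$delta_f)
})

test_that("isotropic-only field centers the intra peak at zero", {
  fx <- small_packing_fixture()
  orient <- orientation_map(fx$map)
  chi <- build_tensor_map(fx$map, orient,
                          compartment_properties(chi_iso = -100,
                                                 chi_aniso = 0))
  fld <- reference_field(forward_field(chi), fx$map)
  h <- compartment_histograms(fld, fx$map)
  expect_equal(h$peaks$peak_hz[h$peaks$compartment == "intra"], 0,
               tolerance = 0.5)
  # myelin shifts positive for diamagnetic chi under perpendicular field
  expect_gt(h$peaks$mean_hz[h$peaks$compartment == "myelin"], 0)
})

test_that("wedge and continuous orientations give near-identical fields", {
  fx <- single_axon_fixture()
  f_cont <- single_axon_field()
  or_w <- orientation_map(fx$map, mode = "wedge")
  f_wedge <- forward_field(build_tensor_map(fx$map, or_w))
  intra <- fx$map$labels == 1L
  expect_lt(abs(mean(f_cont$delta_f[intra]) - mean(f_wedge$delta_f[intra])),
            0.5)
})

test_that("wedge mode quantizes phi to the requested wedge count", {
  fx <- single_axon_fixture()
  orw <- orientation_map(fx$map, mode = "wedge", n_wedges = 4)
  vals <- sort(unique(orw$phi[!is.na(orw$phi)]))
  expect_equal(vals, pi / 4 + (0:3) * pi / 2, tolerance = 1e-12)
  # continuous mode: pixel due east of centroid has phi ~ 0
  orc <- orientation_map(fx$map)
  ctr_px <- round(3 / fx$grid$pixel_size)
  east <- ctr_px + round(0.45 / fx$grid$pixel_size)
  expect_lt(min(orc$phi[east, ctr_px], 2 * pi - orc$phi[east, ctr_px]), 0.02)
})
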