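test_that("spin seeding is deterministic, weighted and compartment-aware", {
  fx <- small_packing_fixture()
  cfg <- diffusion_config(n_spins = 2000, seed = 5)
  sp1 <- init_spins(fx$map, sample_mask(fx$grid, 0.5), cfg)
  sp2 <- init_spins(fx$map, sample_mask(fx$grid, 0.5), cfg)
  expect_identical(sp1$x, sp2$x)
  expect_true(all(sp1$weight[sp1$home == 2L] == 0.5))
  expect_true(all(sp1$weight[sp1$home != 2L] == 1))
  expect_true(all(!sp1$mobile[sp1$home == 2L]))
  # single-compartment map: all weights one
  uni <- label_map(matrix(1L, 64, 64), grid_spec(64, 4))
  spu <- init_spins(uni, sample_mask(grid_spec(64, 4), 1), cfg)
  expect_true(all(spu$weight == 1))
  expect_error(init_spins(fx$map, cfg = diffusion_config(n_spins = 0)))
})

test_that("free diffusion recovers D from the Einstein relation", {
  grid <- grid_spec(128, 100)  # obstacle-free, periodic
  map <- label_map(matrix(0L, 128, 128), grid, periodic = TRUE)
  zf <- field_map(matrix(0, 128, 128), grid, periodic = TRUE)
  cfg <- diffusion_config(n_spins = 8000, D_free = 2, step_time = 0.05,
                          n_steps = 300, seed = 9)
  sp <- init_spins(map, sample_mask(grid, 0.3), cfg)
  x0 <- sp$x; y0 <- sp$y
  dx <- numeric(length(x0)); dy <- numeric(length(y0))
  with_seed <- wmgre:::with_seed
  with_seed(99, {
    for (k in seq_len(cfg$n_steps)) {
      xp <- sp$x; yp <- sp$y
      sp <- step_ensemble(sp, map, zf, cfg, dt = cfg$step_time)
      # accumulate unwrapped displacements (periodic map wraps positions)
      ddx <- sp$x - xp; ddy <- sp$y - yp
      ddx <- ddx - 100 * round(ddx / 100); ddy <- ddy - 100 * round(ddy / 100)
      dx <- dx + ddx; dy <- dy + ddy
    }
  })
  msd <- mean(dx^2 + dy^2)
  t_tot <- cfg$n_steps * cfg$step_time
  expect_lt(abs(msd / (4 * t_tot) / cfg$D_free - 1), 0.05)
  # phases stay zero in a zero field
  expect_true(all(sp$phase == 0))
})

test_that("uniform field accrues the exact closed-form phase", {
  grid <- grid_spec(64, 10)
  map <- label_map(matrix(0L, 64, 64), grid, periodic = TRUE)
  fc <- field_map(matrix(7, 64, 64), grid, periodic = TRUE)
  cfg <- diffusion_config(n_spins = 50, step_time = 0.5, n_steps = 20,
                          seed = 3)
  sp <- init_spins(map, sample_mask(grid, 0.5), cfg)
  for (k in 1:20) sp <- step_ensemble(sp, map, fc, cfg, dt = 0.5)
  expect_equal(sp$phase, rep(2 * pi * 7 * 10 / 1000, 50), tolerance = 1e-12)
})

test_that("myelin is impermeable under the reject rule", {
  fx <- small_packing_fixture()
  zf <- field_map(matrix(0, fx$grid$n, fx$grid$n), fx$grid, periodic = TRUE)
  cfg <- diffusion_config(n_spins = 3000, step_time = 0.002, seed = 21)
  sp <- init_spins(fx$map, sample_mask(fx$grid, 0.5), cfg)
  home <- sp$home
  for (k in 1:50) sp <- step_ensemble(sp, fx$map, zf, cfg, dt = 0.002)
  n_px <- fx$grid$n; px <- fx$grid$pixel_size
  ii <- pmin(pmax(floor(sp$x / px), 0), n_px - 1) + 1
  jj <- pmin(pmax(floor(sp$y / px), 0), n_px - 1) + 1
  land <- fx$map$labels[(jj - 1) * n_px + ii]
  expect_true(all(land[home != 2L] != 2L))
  # immobile myelin spins have not moved
  expect_true(all(sp$x[home == 2L] == init_spins(fx$map,
    sample_mask(fx$grid, 0.5), cfg)$x[home == 2L]))
})

test_that("D -> 0 limit reproduces the static signal at seed positions", {
  fx <- small_packing_fixture()
  orient <- orientation_map(fx$map)
  chi <- build_tensor_map(fx$map, orient)
  fld <- reference_field(forward_field(chi), fx$map)
  mask <- sample_mask(fx$grid, 0.5)
  echoes <- echo_times("static")
  cfg <- diffusion_config(n_spins = 40000, D_free = 1e-9, step_time = 1,
                          seed = 4)
  dsig <- run_diffusion(fx$map, fld, cfg, echoes = echoes, mask = mask)
  ssig <- static_signal(fld, fx$map, echoes = echoes, mask = mask)
  # Monte Carlo estimate of the pixel sum: agreement to sampling error;
  # phase compared mid-curve (the late-echo beat null makes phase there
  # ill-conditioned for any estimator)
  expect_lt(max(abs(dsig$magnitude - ssig$magnitude)), 0.02)
  k30 <- which.min(abs(echoes - 30))
  expect_lt(abs(dsig$phase_rad[k30] - ssig$phase_rad[k30]), 0.05)
})

test_that("diffusion run conserves spins and is reproducible", {
  fx <- small_packing_fixture()
  zf <- field_map(matrix(1.5, fx$grid$n, fx$grid$n), fx$grid,
                  periodic = TRUE)
  cfg <- diffusion_config(n_spins = 500, time_scale = 30, seed = 8)
  s1 <- run_diffusion(fx$map, zf, cfg, echoes = seq(0, 55, 5))
  s2 <- run_diffusion(fx$map, zf, cfg, echoes = seq(0, 55, 5))
  expect_identical(s1$magnitude, s2$magnitude)
  e1 <- attr(s1, "ensemble")
  expect_length(e1$x, 500)
  expect_equal(sum(e1$weight), sum(attr(s2, "ensemble")$weight))
  # zero-field map: magnitude equals the relaxation envelope to MC error
  props <- compartment_properties()
  cnt <- tabulate(fx$map$labels[sample_mask(fx$grid)$mask] + 1L, 3)
  env <- vapply(s1$time_ms, function(t)
    sum(props$rho * cnt * exp(-t / props$T2_ms)) / sum(props$rho * cnt),
    numeric(1))
  expect_lt(max(abs(s1$magnitude - env)), 0.02)
})

test_that("echo snapshots interpolate between steps", {
  grid <- grid_spec(32, 5)
  map <- label_map(matrix(0L, 32, 32), grid, periodic = TRUE)
  fc <- field_map(matrix(10, 32, 32), grid, periodic = TRUE)
  cfg <- diffusion_config(n_spins = 10, step_time = 1.3, n_steps = 50,
                          seed = 2)
  sig <- run_diffusion(map, fc, cfg, echoes = c(0, 10, 20, 41.5, 55))
  expect_equal(sig$phase_rad, 2 * pi * 10 * c(0, 10, 20, 41.5, 55) / 1000,
               tolerance = 1e-9)
  expect_error(run_diffusion(map, fc, cfg, echoes = c(0, 80)), "beyond")
})
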