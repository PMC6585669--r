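# Shared small fixtures, built once per test run.

# Single nested-circle axon, well resolved (r_outer ~ 83 px).
single_axon_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- grid_spec(1000, 6)
      ax <- make_single_ellipse_axon(ellipse_spec(0), g = 0.7, grid = grid)
      map <- rasterize(ax, grid)
      cache <<- list(grid = grid, axons = ax, map = map)
    }
    cache
  }
})

# Small packed geometry (same pixel size and composition as the full model,
# scaled down in fiber count and extent).
small_packing_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- packing_config(n_axons = 120, extent = 10.7, seed = 42)
      ax <- pack_circles(cfg)
      grid <- grid_spec(644, 10.7)
      map <- rasterize(ax, grid)
      cache <<- list(config = cfg, axons = ax, grid = grid, map = map)
    }
    cache
  }
})

# Field of the single axon under the reference configuration.
single_axon_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- single_axon_fixture()
      orient <- orientation_map(fx$map)
      chi <- build_tensor_map(fx$map, orient)
      cache <<- forward_field(chi)
    }
    cache
  }
})

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
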