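# Full-scale reference-condition fixture shared by the acceptance tests: the
# 1434-fiber packed circular model on the 37 um domain, rasterized at half
# the native reference resolution (2227 px; same physics, 4x faster
# transforms).
# Built once per test run.
full_scale_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(seed = 20260927)
      ax <- pack_circles(wmgre:::exp_packing(cfg,
                                             wmgre:::child_seed(cfg$seed, 1L)))
      grid <- grid_spec(cfg$grid_n, cfg$extent)
      map <- rasterize(ax, grid)
      cache <<- list(cfg = cfg, axons = ax, grid = grid, map = map)
    }
    cache
  }
})
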