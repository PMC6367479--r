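# Shared small objects, built once per test run.
fx_grid <- make_frequency_grid(0.5, 20, 64)
fx_elev <- make_elevation_grid()
fx_hrtfs <- make_canonical_hrtfs(hrtf_params(), fx_grid, fx_elev)
fx_cfg <- model_config()

# Brute-force MAE-regression oracle: scan gains on a fixed grid; for each
# gain the optimal intercept is exactly the median residual, so the scan
# finds the global optimum to the gain-grid resolution.
oracle_mae <- function(targets, responses, g_range = c(-2, 2), g_step = 0.001) {
  gs <- seq(g_range[1], g_range[2], by = g_step)
  best <- c(obj = Inf, g = NA, b = NA)
  for (g in gs) {
    b <- stats::median(responses - g * targets)
    o <- mean(abs(responses - g * targets - b))
    if (o < best["obj"]) best <- c(obj = o, g = g, b = b)
  }
  best
}
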