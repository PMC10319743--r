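# Shared fixtures, built once per test run.

# healthy-phantom baseline scans on the simulated grid (both polarizations)
healthy_phantom <- arm_phantom()
baseline_scan_sim <- raster_scan(healthy_phantom, scan_grid("sim"))

scan_with_crack <- function(crack, grid = scan_grid("sim"), phantom_args = list(),
                            ...) {
  ph <- do.call(arm_phantom, c(phantom_args, list(crack = crack)))
  raster_scan(ph, grid, ...)
}

classify_case <- function(crack, baseline = baseline_scan_sim,
                          phantom_args = list(), threshold_deg = 2) {
  sc <- scan_with_crack(crack, phantom_args = phantom_args)
  classify_crack(
    phase_image(sc, baseline, pol = "x"),
    phase_image(sc, baseline, pol = "y"),
    threshold_deg
  )
}

grid_step <- function(x) if (length(x) > 1) diff(x)[1] else Inf
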