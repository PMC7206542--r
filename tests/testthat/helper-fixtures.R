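# Shared fixtures: small detector geometries and model curves.

fix_geom <- function(distance = 300, shape = c(128, 128), pixel = 0.7,
                     bc = c(0, 0), label = "det", energy = 13.5) {
  xs_geometry(distance = distance, beam_center = bc, pixel_size = pixel,
              shape = shape, energy = energy, label = label)
}

# counts-scale water model as a plain intensity function
fix_water_model <- function(amplitude = 500) {
  function(q) water_intensity(q, amplitude = amplitude)
}

# Poisson-noised profile on a grid (emulating an averaged measurement at a
# given counting scale)
fix_noisy_profile <- function(I, q, scale = 2000) {
  lam <- I * scale
  xs_profile(q, rpois(length(lam), lam) / scale,
             sigma = sqrt(pmax(lam, 1)) / scale)
}

# standard single-species drifting run; named arguments override the defaults
fix_sec_spec <- function(...) {
  args <- list(
    species = list(list(model = function(q) 0.6 * sphere_intensity(q, 30),
                        center = 600, width = 40, conc = 1)),
    drift_alpha = 0.001, frame_interval = 2, run_length = 1200,
    counts_scale = 500, uv_offset = 30)
  over <- list(...)
  args[names(over)] <- over
  do.call(sec_run_spec, args)
}
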