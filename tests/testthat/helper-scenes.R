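# Shared synthetic study conditions.
#
# The pipeline-recovery scene is a dense, bright, axis-aligned suspension:
# total particle signal must dominate the noise-induced tophat floor for the
# sum-of-gray proxy to track the true relative gray mass, and axis-aligned
# orientations make the mean projected extent analytically exact.

recovery_population <- function(n_particles = 120) {
  particle_population_spec(
    n_particles = n_particles,
    length_median_um = 170, length_log_sd = 0.25,
    width_median_um = 50, width_log_sd = 0.2,
    intensity_range = c(235, 250),
    orientations = c(0, 90),
    fraction_recalcitrant = 0.45)
}

recovery_imaging <- function(seed, n_replicates = 3,
                             time_points_h = c(0, 0.25, 0.5, 0.75, 1, 2, 3, 4, 5, 7)) {
  imaging_config(height_px = 256, width_px = 256, pixel_size_um = 8.2,
                 n_replicates = n_replicates, time_points_h = time_points_h,
                 background_amplitude = 8, background_scale_px = 600,
                 noise_sd = 2, allow_overlap = FALSE, seed = seed)
}

dissolve_scenario <- function() {
  # hazard 0.172/h: 30% of degradable particles survive 7 h
  degradation_scenario("dissolve", dissolve_hazard_per_h = 0.172,
                       sugar_max_yield_pct = 37)
}

shrink_scenario <- function() {
  degradation_scenario("shrink", shrink_rate_um_per_h = 3,
                       sugar_max_yield_pct = 37)
}
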