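test_that("no-degradation scenario keeps truth and frame mass constant", {
  spec <- recovery_population(n_particles = 20)
  scen <- degradation_scenario("dissolve", dissolve_hazard_per_h = 0)
  img <- imaging_config(height_px = 128, width_px = 128, n_replicates = 2,
                        time_points_h = c(0, 1, 3), background_amplitude = 0,
                        noise_sd = 0, allow_overlap = FALSE, seed = 4)
  sim <- simulate_time_lapse(spec, scen, img)
  expect_true(all(sim$truth$n_particles == sim$truth$n_particles[1]))
  expect_equal(sim$truth$mass_ratio, rep(1, 3))
  expect_equal(sim$truth$mean_length_um, rep(sim$truth$mean_length_um[1], 3))
  expect_equal(sim$truth$sugar_pct, rep(0, 3))
  # positions are redrawn per frame (stirring) but noiseless total mass is
  # conserved exactly across times and replicates
  masses <- unlist(lapply(sim$frames, function(fs) vapply(fs, total_gray, 1)))
  expect_equal(max(masses) - min(masses), 0, tolerance = 1e-6 * masses[1])
})

test_that("shrink-only truth follows linear shrinkage until extinction", {
  spec <- particle_population_spec(n_particles = 1, length_median_um = 200,
                                   length_log_sd = 0, width_median_um = 40,
                                   width_log_sd = 0, orientations = 0,
                                   fraction_recalcitrant = 0)
  scen <- degradation_scenario("shrink", shrink_rate_um_per_h = 10)
  img <- imaging_config(height_px = 64, width_px = 64, n_replicates = 1,
                        time_points_h = c(0, 1, 2, 3.5, 5), seed = 1)
  sim <- simulate_time_lapse(spec, scen, img, render = FALSE)
  expect_equal(sim$truth$mean_length_um[1:4], 200 - 10 * c(0, 1, 2, 3.5))
  # width 40 um hits zero at t = 4 h: the particle is extinct at 5 h
  expect_equal(sim$truth$n_particles, c(1L, 1L, 1L, 1L, 0L))
})

test_that("dissolve-only survival matches the closed-form expectation over seeds", {
  f_recal <- 0.45; hazard <- 0.172; t_end <- 7
  expected <- f_recal + (1 - f_recal) * exp(-hazard * t_end)
  spec <- recovery_population(n_particles = 150)
  scen <- degradation_scenario("dissolve", dissolve_hazard_per_h = hazard)
  ratios <- sizes0 <- sizes7 <- numeric(120)
  for (s in seq_len(120)) {
    img <- imaging_config(height_px = 256, width_px = 256, n_replicates = 1,
                          time_points_h = c(0, t_end), seed = 1000 + s)
    sim <- simulate_time_lapse(spec, scen, img, render = FALSE)
    ratios[s] <- sim$truth$count_ratio[2]
    sizes0[s] <- sim$truth$mean_projected_um[1]
    sizes7[s] <- sim$truth$mean_projected_um[2]
  }
  expect_lt(abs(mean(ratios) - expected), 0.03)
  # dissolution removes whole particles: mean size is unchanged in expectation
  expect_lt(abs(mean(sizes7) / mean(sizes0) - 1), 0.02)
})

test_that("noiseless non-overlapping frames conserve per-particle mass", {
  spec <- particle_population_spec(n_particles = 15, length_median_um = 150,
                                   length_log_sd = 0.3, width_median_um = 45,
                                   width_log_sd = 0.2, intensity_range = c(200, 200),
                                   fraction_recalcitrant = 1)
  scen <- degradation_scenario("dissolve")
  img <- imaging_config(height_px = 256, width_px = 256, n_replicates = 1,
                        time_points_h = c(0, 1), background_amplitude = 0,
                        noise_sd = 0, allow_overlap = FALSE, seed = 9)
  sim <- simulate_time_lapse(spec, scen, img)
  got_area_px <- total_gray(sim$frames[[1]][[1]]) / 200
  true_area_px <- sim$truth$total_area_um2[1] / 8.2^2
  expect_lt(abs(got_area_px - true_area_px), 15) # +- 1 px^2 per particle
})

test_that("sugar release is monotone, bounded, and plateaus at the configured yield", {
  spec <- recovery_population(n_particles = 80)
  scen <- degradation_scenario("dissolve", dissolve_hazard_per_h = 5,
                               sugar_max_yield_pct = 37)
  img <- imaging_config(height_px = 256, width_px = 256, n_replicates = 1,
                        time_points_h = c(0, 0.5, 1, 2, 4, 7, 10), seed = 2)
  sim <- simulate_time_lapse(spec, scen, img, render = FALSE)
  expect_true(all(diff(sim$truth$sugar_pct) >= 0))
  expect_true(all(sim$truth$sugar_pct <= 37 + 1e-9))
  # hazard 5/h: essentially all degradable volume gone by 10 h
  expect_gt(sim$truth$sugar_pct[7], 36.5)
})

test_that("fragmentation conserves area while increasing the count", {
  spec <- particle_population_spec(n_particles = 30, length_median_um = 150,
                                   length_log_sd = 0.2, width_median_um = 40,
                                   width_log_sd = 0.1, fraction_recalcitrant = 0)
  scen <- degradation_scenario("fragment", fragment_rate_per_h = 2,
                               fragment_counts = c(2L, 3L))
  img <- imaging_config(height_px = 256, width_px = 256, n_replicates = 1,
                        time_points_h = c(0, 2), seed = 12)
  sim <- simulate_time_lapse(spec, scen, img, render = FALSE)
  expect_gt(sim$truth$n_particles[2], sim$truth$n_particles[1])
  expect_equal(sim$truth$total_area_um2[2], sim$truth$total_area_um2[1])
  expect_equal(sim$truth$sugar_pct[2], 0) # fragmentation releases no sugar
  expect_lt(sim$truth$mean_length_um[2], sim$truth$mean_length_um[1])
})

test_that("identical seed and configuration reproduce outputs bit for bit", {
  spec <- recovery_population(n_particles = 25)
  scen <- dissolve_scenario()
  img <- imaging_config(height_px = 96, width_px = 96, n_replicates = 2,
                        time_points_h = c(0, 1), seed = 33)
  s1 <- simulate_time_lapse(spec, scen, img)
  s2 <- simulate_time_lapse(spec, scen, img)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$frames, s2$frames)
})

test_that("invalid configurations are rejected", {
  expect_error(particle_population_spec(n_particles = 0), "n_particles")
  expect_error(particle_population_spec(fraction_recalcitrant = 1.2), "recalcitrant")
  expect_error(particle_population_spec(intensity_range = c(0, 300)), "intensity")
  expect_error(degradation_scenario("dissolve", dissolve_hazard_per_h = -1), "rates")
  expect_error(degradation_scenario("dissolve", sugar_max_yield_pct = 150), "sugar")
  expect_error(imaging_config(time_points_h = c(-1, 0, 1)), "negative")
  expect_error(imaging_config(time_points_h = c(1, 2)), "start at 0")
  spec <- particle_population_spec(n_particles = 2, length_median_um = 5000,
                                   length_log_sd = 0)
  expect_error(
    simulate_time_lapse(spec, dissolve_scenario(),
                        imaging_config(height_px = 128, width_px = 128,
                                       time_points_h = c(0, 1), seed = 1)),
    "larger than frame")
})
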