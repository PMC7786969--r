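test_that("the decay kernel matches scalar evaluation", {
  g <- t2_grid(50, 0.1, 1000)
  tt <- seq(0.2, 20, by = 0.2)
  K <- build_kernel(tt, g)
  expect_true(all(K > 0 & K <= 1))
  expect_equal(build_kernel(0, g)[1, ], rep(1, 50), ignore_attr = TRUE)
  set.seed(8)
  for (s in 1:5) {
    i <- sample(length(tt), 1); j <- sample(50, 1)
    expect_equal(K[i, j], exp(-tt[i] / g[j]))
  }
  # t = T2 -> 1/e
  expect_equal(build_kernel(5, 5)[1, 1], exp(-1))
})

test_that("zero decay inverts to a zero spectrum", {
  d <- cpmg_decay(seq(0.2, 20, by = 0.2), rep(0, 100))
  sp <- ilt(d, t2_grid(60, 0.1, 1000), lambda = 1e-6)
  expect_true(all(sp$raw_amplitude == 0))
  expect_equal(nrow(sp$components), 0)
})

test_that("noiseless mono-exponential decay concentrates at the true T2", {
  truth <- ground_truth_t2(data.frame(t2_ms = 10, log_sd = 0, weight = 1),
                           total_water_content = 50)
  d <- simulate_cpmg(truth, 0.2, 1024, noise_sd = 0)
  grid <- t2_grid()
  sp <- ilt(d, grid, lambda = 1e-8)
  step <- diff(log(as.numeric(grid)))[1]
  near <- abs(log(sp$t2_ms) - log(10)) <= step * (1 + 1e-9)
  expect_gte(sum(sp$raw_amplitude[near]) / sum(sp$raw_amplitude), 0.95)
  # total spectral mass conserves the t -> 0 amplitude within 2%
  expect_equal(sum(sp$raw_amplitude), 50, tolerance = 0.02)
  expect_true(all(sp$raw_amplitude >= 0))
})

test_that("two well-separated components are resolved with correct proportions", {
  truth <- ground_truth_t2(data.frame(t2_ms = c(2, 100), log_sd = 0,
                                      weight = c(0.5, 0.5)),
                           total_water_content = 50, moisture_content = 50)
  d <- simulate_cpmg(truth, 0.2, 2048, noise_sd = 50 / 1000, seed = 3)
  sp <- ilt(d, lambda = "auto")
  expect_equal(nrow(sp$components), 2)
  expect_equal(sp$components$p2, c(0.5, 0.5), tolerance = 0.1)
  expect_equal(sp$components$peak_t2_ms[1], 2, tolerance = 0.3)
  expect_equal(sp$components$peak_t2_ms[2], 100, tolerance = 15)
  expect_equal(sum(sp$components$p2), 1, tolerance = 1e-6)
})

test_that("auto lambda satisfies the discrepancy bound and grows with noise", {
  truth <- ground_truth_t2(data.frame(t2_ms = c(5, 80), log_sd = 0.1,
                                      weight = c(0.6, 0.4)),
                           total_water_content = 40, moisture_content = 40)
  d1 <- simulate_cpmg(truth, 0.2, 1024, noise_sd = 0.04, seed = 21)
  d2 <- simulate_cpmg(truth, 0.2, 1024, noise_sd = 0.08, seed = 21)
  l1 <- select_lambda(d1); l2 <- select_lambda(d2)
  expect_gte(l2, l1)
  sp1 <- ilt(d1, lambda = l1)
  expect_lte(sp1$fit_residual_norm, 1.1 * 0.04 * sqrt(sp1$n_echoes_used))
  # noiseless decay: the near-zero residual target drives lambda to the
  # bottom of the search grid
  d0 <- simulate_cpmg(truth, 0.2, 512, noise_sd = 0)
  l0 <- suppressWarnings(select_lambda(d0))
  expect_lt(l0, l1)
})

test_that("a noise-only decay yields near-zero spectral mass", {
  set.seed(77)
  tt <- seq(0.2, 102.4, by = 0.2)
  d <- cpmg_decay(tt, rnorm(length(tt), 0, 0.05), noise_sd_estimate = 0.05)
  sp <- ilt(d, lambda = "auto")
  expect_lt(sum(sp$raw_amplitude), 5 * 0.05)
})

test_that("long decays are thinned logarithmically before inversion", {
  truth <- ground_truth_t2(data.frame(t2_ms = 50, log_sd = 0, weight = 1),
                           total_water_content = 30)
  d <- simulate_cpmg(truth, 0.2, 20000, noise_sd = 0.03, seed = 5)
  sp <- ilt(d, lambda = 1e-4)
  expect_lte(sp$n_echoes_used, 2000)
  i_max <- which.max(sp$raw_amplitude)
  expect_equal(sp$t2_ms[i_max], 50, tolerance = 0.1)
})

test_that("component detection handles single and symmetric double bumps", {
  grid <- t2_grid(120, 0.1, 1000)
  g <- as.numeric(grid)
  mk <- function(amp) {
    structure(list(t2_ms = g, amplitude = amp, raw_amplitude = amp,
                   components = NULL, lambda_used = 0, fit_residual_norm = 0,
                   noise_sd = NULL, moisture_content = NULL,
                   n_echoes_used = length(g)),
              class = "t2_spectrum")
  }
  one <- exp(-(log(g) - log(10))^2 / 0.1)
  c1 <- detect_components(mk(one))
  expect_equal(nrow(c1), 1)
  expect_equal(c1$p2, 1)
  two <- exp(-(log(g) - log(1))^2 / 0.05) + exp(-(log(g) - log(100))^2 / 0.05)
  c2 <- detect_components(mk(two))
  expect_equal(nrow(c2), 2)
  expect_equal(c2$p2, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(nrow(detect_components(mk(rep(0, length(g))))), 0)
})

test_that("pore calibration is exact on collinear standards", {
  st <- data.frame(t2_ms = c(2, 10, 40, 90), diameter_nm = 1 + 0.5 * c(2, 10, 40, 90))
  cal <- fit_pore_calibration(st)
  expect_equal(cal$r2, 1)
  expect_equal(cal$slope_nm_per_ms, 0.5)
  expect_equal(cal$intercept_nm, 1)
  expect_error(fit_pore_calibration(st[1, ]), ">= 2")
  expect_error(fit_pore_calibration(data.frame(t2_ms = c(2, 2),
                                               diameter_nm = c(1, 3))), "duplicate")
})

test_that("noisy calibration matches the normal-equation oracle", {
  set.seed(14)
  st <- data.frame(t2_ms = c(3, 12, 28, 70),
                   diameter_nm = 2 + 0.4 * c(3, 12, 28, 70) + rnorm(4, 0, 0.5))
  cal <- fit_pore_calibration(st)
  o <- oracle_ols(st$t2_ms, st$diameter_nm)
  expect_equal(cal$slope_nm_per_ms, o$slope, tolerance = 1e-12)
  expect_equal(cal$intercept_nm, o$intercept, tolerance = 1e-12)
  expect_equal(cal$r2, o$r2, tolerance = 1e-12)
})

test_that("the default calibration maps the published anchor points exactly", {
  cal <- default_pore_calibration()
  expect_equal(cal$slope_nm_per_ms, 5 / 13)
  expect_equal(cal$intercept_nm, 45 / 13)
  expect_equal(as.numeric(t2_to_pore(cal, 4)), 5)
  expect_equal(as.numeric(t2_to_pore(cal, 30)), 15)
  ident <- fit_pore_calibration(data.frame(t2_ms = c(1, 2, 3),
                                           diameter_nm = c(1, 2, 3)))
  expect_equal(as.numeric(t2_to_pore(ident, 7.5)), 7.5)
  # diameter strictly increasing in T2 under any valid calibration
  d <- t2_to_pore(cal, as.numeric(t2_grid(50)))
  expect_true(all(diff(d) > 0))
})

test_that("water in the enzyme-accessible pore band is a masked sum", {
  grid <- t2_grid(100, 0.5, 500)
  g <- as.numeric(grid)
  cal <- default_pore_calibration()
  amp <- exp(-(log(g) - log(10))^2 / 0.2)
  amp <- amp / sum(amp) * 42
  sp <- structure(list(t2_ms = g, amplitude = amp, raw_amplitude = amp,
                       components = NULL, lambda_used = 0, fit_residual_norm = 0,
                       noise_sd = NULL, moisture_content = 42,
                       n_echoes_used = 100),
                  class = "t2_spectrum")
  d <- t2_to_pore(cal, g)
  oracle <- sum(amp[d >= 5 & d < 15])
  expect_equal(as.numeric(water_in_pore_band(sp, cal)), oracle)
  # spectrum entirely inside the band equals the total water content
  inside <- g >= 4.5 & g < 29
  amp2 <- ifelse(inside, 1, 0); amp2 <- amp2 / sum(amp2) * 42
  sp2 <- sp; sp2$amplitude <- amp2
  expect_equal(as.numeric(water_in_pore_band(sp2, cal)), 42)
  # spectrum entirely above the band gives zero
  amp3 <- ifelse(d >= 15, 1, 0)
  sp3 <- sp; sp3$amplitude <- amp3
  expect_equal(as.numeric(water_in_pore_band(sp3, cal)), 0)
})

test_that("CPMG forward model follows its closed form", {
  tr <- ground_truth_t2(data.frame(t2_ms = 10, log_sd = 0, weight = 1),
                        total_water_content = 7)
  d <- simulate_cpmg(tr, 0.5, 20, noise_sd = 0)
  expect_equal(d$amplitudes, 7 * exp(-d$times_ms / 10))
  tr2 <- ground_truth_t2(data.frame(t2_ms = c(2, 100), log_sd = 0,
                                    weight = c(0.5, 0.5)), total_water_content = 1)
  d2 <- simulate_cpmg(tr2, 0.2, 5, noise_sd = 0)
  expect_equal(d2$amplitudes[1],
               0.5 * exp(-0.2 / 2) + 0.5 * exp(-0.2 / 100))
  tr0 <- ground_truth_t2(data.frame(t2_ms = 10, log_sd = 0, weight = 1),
                         total_water_content = 0)
  expect_true(all(simulate_cpmg(tr0, 0.2, 10)$amplitudes == 0))
  expect_error(simulate_cpmg(tr, 0.2, 10, noise_sd = -1), "noise_sd")
  expect_error(ground_truth_t2(data.frame(t2_ms = -1, log_sd = 0, weight = 1)),
               "T2 centers")
  expect_error(ground_truth_t2(data.frame(t2_ms = c(1, 2), log_sd = 0,
                                          weight = c(0.5, 0.6))), "sum to 1")
})

test_that("multi-modal distributions at high moisture recover the component count", {
  comp <- data.frame(t2_ms = c(1.2, 8, 40, 200, 1500),
                     log_sd = rep(0.12, 5),
                     weight = c(0.15, 0.2, 0.25, 0.25, 0.15))
  truth <- ground_truth_t2(comp, total_water_content = 67, moisture_content = 67)
  d <- simulate_cpmg(truth, 0.2, 8000, noise_sd = 67 / 5000, seed = 31)
  sp <- ilt(d, lambda = "auto")
  expect_gte(nrow(sp$components), 4)
  expect_lte(nrow(sp$components), 6)
  expect_true(all(sp$raw_amplitude >= 0))
})
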