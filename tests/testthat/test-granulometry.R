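bar_image <- function(nrow = 64, ncol = 64, bars, level = 100, thick = 1) {
  # bars: list of c(row, col_start, length_px)
  m <- matrix(0, nrow, ncol)
  for (b in bars) m[b[1]:(b[1] + thick - 1), b[2]:(b[2] + b[3] - 1)] <- level
  gray_image(m)
}

test_that("pattern spectrum of a single bar is analytic", {
  img <- bar_image(bars = list(c(20, 10, 10)))       # 1 px thick, 10 px long
  cv <- graylevel_granulometry(img, max_size_px = 30, step_px = 2)
  # 0 deg: whole mass (1000) in the 10 px bin; 90 deg: in the 2 px (= first) bin;
  # averaged curve holds half the mass in each
  expect_equal(cv$density[cv$size_um == 10 * 8.2], 500)
  expect_equal(cv$density[cv$size_um == 2 * 8.2], 500)
  expect_equal(sum(cv$density), 1000)
  expect_equal(cv$residual_mass, 0)
})

test_that("bar masses scale with bar area", {
  img <- bar_image(bars = list(c(10, 5, 10), c(40, 5, 20)))
  cv <- graylevel_granulometry(img, max_size_px = 30, step_px = 2)
  m10 <- cv$density[cv$size_um == 10 * 8.2]
  m20 <- cv$density[cv$size_um == 20 * 8.2]
  expect_equal(m20 / m10, 2)
})

test_that("empty image yields a zero curve, not an error", {
  cv <- graylevel_granulometry(gray_image(matrix(0, 32, 32)))
  expect_true(all(cv$density == 0))
  expect_equal(cv$residual_mass, 0)
  expect_error(graylevel_mean_size(cv), "undefined")
})

test_that("granulometry sieves: density is non-negative on random images", {
  set.seed(202)
  for (i in 1:10) {
    m <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
    cv <- graylevel_granulometry(gray_image(m), max_size_px = 20, step_px = 2)
    expect_true(all(cv$density >= 0))
    # mass balance: bins + residual = total
    expect_equal(sum(cv$density) + cv$residual_mass, cv$total)
  }
})

test_that("normalization identities hold", {
  img <- bar_image(bars = list(c(10, 5, 12), c(30, 5, 6)))
  cv <- graylevel_granulometry(img, max_size_px = 30)
  self <- normalize_curve(cv, "self")
  expect_equal(sum(self$density) + self$residual_mass, 1)
  # T0 normalization of the T0 curve itself equals self normalization
  t0 <- normalize_curve(cv, "T0", ref_total = cv$total)
  expect_equal(t0$density, self$density)
  # half-intensity frame under T0 normalization has half the curve total
  half <- graylevel_granulometry(gray_image(unclass(img) / 2), max_size_px = 30)
  half_t0 <- normalize_curve(half, "T0", ref_total = cv$total)
  expect_equal(sum(half_t0$density), 0.5 * sum(self$density))
  expect_error(normalize_curve(cv, "T0", ref_total = 0), "positive")
  expect_error(normalize_curve(self, "self"), "already normalized")
})

test_that("average_curves is the pointwise mean and checks grids", {
  img <- bar_image(bars = list(c(10, 5, 12)))
  cv <- graylevel_granulometry(img, max_size_px = 20)
  expect_equal(average_curves(list(cv, cv))$density, cv$density)
  zero <- graylevel_granulometry(gray_image(matrix(0, 64, 64)), max_size_px = 20)
  expect_equal(average_curves(list(cv, zero))$density, cv$density / 2)
  set.seed(5)
  curves <- lapply(1:10, function(i) {
    m <- matrix(sample(0:50, 32 * 32, replace = TRUE), 32, 32)
    graylevel_granulometry(gray_image(m), max_size_px = 10)
  })
  avg <- average_curves(curves)
  brute <- rowMeans(sapply(curves, `[[`, "density"))
  expect_equal(avg$density, brute)
  other <- graylevel_granulometry(img, max_size_px = 30)
  expect_error(average_curves(list(cv, other)), "mismatched")
})

test_that("gray-level mean size is the mass-weighted bin mean", {
  img <- bar_image(bars = list(c(10, 5, 10), c(30, 5, 10)), thick = 1)
  # make a curve with all mass in one bin by hand-checking a 10 px bar pair:
  cv <- graylevel_granulometry(img, max_size_px = 20, step_px = 2)
  # mass sits at 82 um (10 px) and 16.4 um (1 px thickness), equally split
  expect_equal(graylevel_mean_size(cv), (82 + 16.4) / 2)
  # single-bin curve: mean equals that bin
  cv1 <- cv; cv1$density[] <- 0; cv1$density[cv$size_um == 10 * 8.2] <- 3
  expect_equal(graylevel_mean_size(cv1), 82)
  # equal mass at 16.4 and 32.8 -> 24.6
  cv2 <- cv; cv2$density[] <- 0
  cv2$density[cv$size_um %in% c(16.4, 32.8)] <- 1
  expect_equal(graylevel_mean_size(cv2), 24.6)
})

test_that("size classes follow the effective-edge convention", {
  img <- bar_image(bars = list(c(10, 5, 3)))   # 3 px = 24.6 um extent
  cv <- graylevel_granulometry(img, max_size_px = 40, step_px = 2)
  scl <- size_class_masses(cv, edges_um = c(0, 45, 225, Inf))
  # all mass below 45 um -> first class only
  expect_equal(scl$class_mass, c(cv$total, 0, 0))
  # effective upper edges are the nearest bin boundary above 45 and 225 um
  full <- graylevel_granulometry(bar_image(bars = list(c(10, 5, 10))),
                                 max_size_px = 131, step_px = 2)
  eff <- size_class_masses(full)$effective_edges_um
  expect_equal(eff[1], 49.2)
  expect_equal(eff[2], 229.6)
  # uniform density: class masses proportional to bin counts per class
  u <- full; u$density[] <- 1; u$residual_mass <- 0
  scl_u <- size_class_masses(u)
  expect_equal(scl_u$class_mass, c(3, 11, 51))
  expect_error(size_class_masses(cv, edges_um = c(0, 225, 45)), "ascending")
})

test_that("class-relative change flags classes empty at T0", {
  # bars of 3, 10 and 30 px populate all three default size classes
  img <- bar_image(nrow = 64, ncol = 64,
                   bars = list(c(10, 5, 3), c(30, 5, 10), c(50, 5, 30)))
  cv <- graylevel_granulometry(img, max_size_px = 60)
  s0 <- size_class_masses(cv)
  expect_equal(class_relative_change(s0, s0), c(1, 1, 1), ignore_attr = TRUE)
  s1 <- s0; s1$class_mass[2] <- s1$class_mass[2] / 2
  expect_equal(class_relative_change(s1, s0), c(1, 0.5, 1), ignore_attr = TRUE)
  s0z <- s0; s0z$class_mass[3] <- 0
  r <- class_relative_change(s1, s0z)
  expect_true(is.na(r[3]))
  expect_true(attr(r, "undefined")[3])
})

test_that("relative particle number tracks constructed mass removal", {
  # 5 identical disjoint bars; removing 1 of 5 drops the ratio to 0.80
  m0 <- matrix(0, 60, 60)
  for (r in seq(5, 45, by = 10)) m0[r, 10:29] <- 100
  m1 <- m0; m1[45, ] <- 0
  f0 <- gray_image(m0); f1 <- gray_image(m1)
  res <- relative_particle_number(list(list(f0, f0), list(f1)), c(0, 1))
  expect_equal(res$relative_particle_number, c(1, 0.8))
  expect_equal(res$n_replicates, c(2L, 1L))
  # empty frame at t gives 0
  res0 <- relative_particle_number(list(list(f0), list(gray_image(matrix(0, 60, 60)))),
                                   c(0, 2))
  expect_equal(res0$relative_particle_number[2], 0)
  expect_error(relative_particle_number(list(list(f0)), 1), "T0")
})
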