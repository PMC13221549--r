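test_that("count-rate calibration divides by the cross-calibration factor", {
  sp <- c(4, 4, 4)
  counts <- volume_grid(array(9.64, c(2, 2, 2)), sp, "cps")
  act <- counts_to_activity(counts, calibration_config(ccf = 9.64))
  expect_equal(act$values, array(1.0, c(2, 2, 2)))

  counts <- volume_grid(array(19.84, c(2, 2, 2)), sp, "cps")
  act <- counts_to_activity(counts, calibration_config(ccf = 9.92))
  expect_equal(act$values, array(2.0, c(2, 2, 2)))

  zero <- volume_grid(array(0, c(2, 2, 2)), sp, "cps")
  expect_true(all(counts_to_activity(zero, calibration_config())$values == 0))

  # wrong quantity tag is refused
  hu <- volume_grid(array(0, c(2, 2, 2)), sp, "HU")
  expect_error(counts_to_activity(hu, calibration_config()),
               class = "voxdosim_format_error")
})

test_that("HU to density interpolates linearly and clamps outside the table", {
  tab <- density_table(c(-1000, 0), c(0.001, 1.0))
  sp <- c(1, 1, 1)
  ct <- volume_grid(array(c(0, -500, -1000, 5000, -2000, 0, 0, 0), c(2, 2, 2)),
                    sp, "HU")
  dens <- hu_to_density(ct, tab)
  expect_identical(dens$quantity, "g_per_cm3")
  expect_equal(dens$values[1, 1, 1], 1.0)       # water anchor
  expect_equal(dens$values[2, 1, 1], 0.5005)    # linear interpolation
  expect_equal(dens$values[1, 2, 1], 0.001)
  expect_equal(dens$values[2, 2, 1], 1.0)       # clamped above
  expect_equal(dens$values[1, 1, 2], 0.001)     # clamped below

  expect_error(density_table(0, 1), class = "voxdosim_format_error")
  expect_error(density_table(c(0, 0), c(1, 1)), class = "voxdosim_format_error")
  expect_error(density_table(c(-100, 100), c(0.9, 1.1)),
               class = "voxdosim_format_error")  # missing water anchor
})

test_that("dose-rate convolution is an impulse response with zero padding", {
  sp <- c(2, 2, 2)
  k <- make_test_kernel(sp, self_fraction = 0.7, range_mm = 3)
  kd <- dim(k$values)

  act <- array(0, c(15, 15, 15)); act[8, 8, 8] <- 1
  rate <- convolve_dose_rate(volume_grid(act, sp, "MBq"), k)
  expect_identical(rate$quantity, "Gy_per_s")
  ctr <- 8; h <- (kd - 1) / 2
  sub <- rate$values[(ctr - h[1]):(ctr + h[1]), (ctr - h[2]):(ctr + h[2]),
                     (ctr - h[3]):(ctr + h[3])]
  expect_equal(sub, k$values)
  expect_equal(sum(rate$values), sum(k$values), tolerance = 1e-12)

  # uniform activity: interior voxels see a * sum(kernel)
  act <- array(2, c(15, 15, 15))
  rate <- convolve_dose_rate(volume_grid(act, sp, "MBq"), k)
  expect_equal(rate$values[8, 8, 8], 2 * sum(k$values), tolerance = 1e-12)

  # zero activity in, zero dose rate out
  zero <- volume_grid(array(0, c(5, 5, 5)), sp, "MBq")
  expect_true(all(convolve_dose_rate(zero, k)$values == 0))

  # kernel spacing must match the grid
  kbad <- make_test_kernel(c(1, 1, 1), 0.7, 3)
  expect_error(convolve_dose_rate(volume_grid(act, sp, "MBq"), kbad),
               class = "voxdosim_kernel_error")
})

test_that("density correction scales dose rate by water/voxel density", {
  sp <- c(2, 2, 2)
  k <- make_test_kernel(sp, self_fraction = 1)
  act <- volume_grid(array(1, c(3, 3, 3)), sp, "MBq")
  dens <- volume_grid(array(2, c(3, 3, 3)), sp, "g_per_cm3")
  r0 <- convolve_dose_rate(act, k)
  r1 <- convolve_dose_rate(act, k, dens)
  expect_equal(r1$values, r0$values / 2)
})

test_that("single-time-point integration applies D = rate * 2t/ln2", {
  sp <- c(2, 2, 2)
  tm <- timing_params(24, 67)

  zero <- volume_grid(array(0, c(3, 3, 3)), sp, "Gy_per_s")
  expect_true(all(hanscheid_integrate(zero, tm)$values == 0))

  # 1 Gy/h at 24 h -> 2*24/ln2 Gy
  rate <- volume_grid(array(1 / 3600, c(3, 3, 3)), sp, "Gy_per_s")
  d <- hanscheid_integrate(rate, tm)
  expect_equal(d$values[1, 1, 1], 2 * 24 / log(2), tolerance = 1e-12)
  expect_identical(d$quantity, "Gy")

  # exact at t = T_eff: estimate equals the true monoexponential integral
  t_eff <- 31
  tm2 <- timing_params(t_eff, t_eff)
  rate0 <- 5e-6  # Gy/s at time zero
  rate_t <- rate0 * 2^(-tm2$t_hours / t_eff)
  est <- hanscheid_integrate(
    volume_grid(array(rate_t, c(2, 2, 2)), sp, "Gy_per_s"), tm2)
  true_integral <- rate0 / (log(2) / (t_eff * 3600))
  expect_equal(est$values[1, 1, 1], true_integral, tolerance = 1e-12)

  # refuses a non-dose-rate input
  dose <- volume_grid(array(1, c(2, 2, 2)), sp, "Gy")
  expect_error(hanscheid_integrate(dose, tm), class = "voxdosim_format_error")
})

test_that("the closed-form bias ratio has the documented shape", {
  # identity at t = T_eff
  expect_equal(underestimation_ratio(timing_params(51, 51)), 1.0)

  # r(x) = x 2^(1-x) peaks at x = 1/ln2 ~ 1.4427
  r <- function(x) x * 2^(1 - x)
  xs <- seq(0.2, 3, by = 0.001)
  expect_equal(xs[which.max(r(xs))], 1 / log(2), tolerance = 1e-3)

  # |1 - r| <= 0.12 across the stated 75-250% validity window
  xw <- seq(0.75, 2.5, by = 0.001)
  expect_true(all(abs(1 - r(xw)) <= 0.12))
  # and the bias exceeds 12% just outside it
  expect_gt(abs(1 - r(0.70)), 0.12)
})

test_that("organ dose statistics summarise masked voxels", {
  sp <- c(1.5, 1.37, 1.37)
  vals <- array(0, c(10, 10, 10))
  vals[1, 1, 1] <- 1; vals[2, 1, 1] <- 2; vals[3, 1, 1] <- 6
  dose <- volume_grid(vals, sp, "Gy")
  m <- array(FALSE, c(10, 10, 10)); m[1:3, 1, 1] <- TRUE
  st <- dose_stats(dose, organ_mask(m, sp, "liver"))
  expect_equal(st$d_mean, 3)
  expect_equal(st$d_max, 6)
  expect_equal(st$d_min, 1)

  uni <- volume_grid(array(2, c(10, 10, 10)), sp, "Gy")
  big <- organ_mask(array(TRUE, c(10, 10, 10)), sp, "liver")
  st <- dose_stats(uni, big)
  expect_equal(c(st$d_mean, st$d_max, st$d_min), c(2, 2, 2))
  expect_equal(st$volume_ml, 1000 * 1.5 * 1.37 * 1.37 / 1000,
               tolerance = 1e-12)

  empty <- organ_mask(array(FALSE, c(10, 10, 10)), sp, "spleen",
                      absent = TRUE)
  expect_error(dose_stats(uni, empty), class = "voxdosim_metric_error")
})

test_that("test kernels are normalised and concentrate with shorter range", {
  sp <- c(4.8, 4.8, 4.8)
  k1 <- make_test_kernel(sp, self_fraction = 1)
  expect_equal(dim(k1$values), c(1L, 1L, 1L))

  k <- make_test_kernel(sp, self_fraction = 0.85, range_mm = 6)
  voxel_kg <- prod(sp) / 1000 * 1e-3
  expected_total <- 0.1475 * 1.602e-13 * 1e6 / voxel_kg
  expect_equal(sum(k$values), expected_total, tolerance = 1e-9)
  ctr <- (dim(k$values) + 1) / 2
  expect_equal(k$values[ctr[1], ctr[2], ctr[3]] / sum(k$values), 0.85,
               tolerance = 1e-9)

  # halving the range concentrates off-centre mass toward the centre:
  # the mass beyond the first shell shrinks
  beyond_first_shell <- function(kern) {
    d <- dim(kern$values); ctr <- (d + 1) / 2
    co <- lapply(1:3, function(ax) (seq_len(d[ax]) - ctr[ax]) * sp[ax])
    r <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`))
    sum(kern$values[r > 1.01 * sp[1]]) / sum(kern$values)
  }
  expect_lt(beyond_first_shell(make_test_kernel(sp, 0.85, 3)),
            beyond_first_shell(make_test_kernel(sp, 0.85, 6)))
})

test_that("the dose pipeline is linear in activity", {
  sp <- c(4, 4, 4)
  k <- make_test_kernel(sp, 0.8, 5)
  tm <- timing_params(24.49, 67)
  act <- array(runif(6^3), c(6, 6, 6))
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  mask <- organ_mask(m, sp, "liver")
  run <- function(a) {
    d <- hanscheid_integrate(
      convolve_dose_rate(volume_grid(a, sp, "MBq"), k), tm)
    dose_stats(d, mask)
  }
  s1 <- run(act); s3 <- run(3 * act)
  expect_equal(s3$d_mean, 3 * s1$d_mean, tolerance = 1e-12)
  expect_equal(s3$d_max, 3 * s1$d_max, tolerance = 1e-12)
  expect_equal(s3$d_min, 3 * s1$d_min, tolerance = 1e-12)
})
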