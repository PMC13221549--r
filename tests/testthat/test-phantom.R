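test_that("phantom construction is deterministic given (config, seed)", {
  cfg <- small_phantom_config()
  a <- build_phantom(cfg, 7)
  b <- build_phantom(cfg, 7)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$activity_true$values, b$activity_true$values)
  expect_identical(lapply(a$masks, `[[`, "values"),
                   lapply(b$masks, `[[`, "values"))
})

test_that("hepatomegaly factor 1 leaves the liver volume unchanged", {
  base <- build_phantom(small_phantom_config(), 1)
  same <- build_phantom(small_phantom_config(hepatomegaly = TRUE,
                                             hepatomegaly_factor = 1), 1)
  expect_equal(sum(same$masks$liver$values), sum(base$masks$liver$values))
  bigger <- build_phantom(small_phantom_config(hepatomegaly = TRUE,
                                               hepatomegaly_factor = 1.25), 1)
  expect_gt(sum(bigger$masks$liver$values), sum(base$masks$liver$values))
})

test_that("overlapping organ ellipsoids are a construction error", {
  cfg <- small_phantom_config()
  cfg$organs$spleen$center <- cfg$organs$liver$center
  expect_error(build_phantom(cfg, 1),
               class = "voxdosim_construction_error")
})

test_that("voxelised sphere activity matches the analytic volume within 5%", {
  # 10 mm sphere at concentration c: total activity ~ c * (4/3) pi r^3
  sph <- sphere_mask(10, c(1, 1, 1))
  conc <- 0.3  # MBq/mL
  act <- sum(sph$values) * prod(sph$spacing) / 1000 * conc
  expect_equal(act, conc * 4 / 3 * pi * 10^3 / 1000, tolerance = 0.05)
})

test_that("renal pelvis is excluded from kidney masks and carries no activity", {
  case <- build_phantom(phantom_config(), 1)
  kid <- case$masks$kidney_right
  # mask has a hole: fewer voxels than the full ellipsoid
  full <- sum(kid$values)
  act_vox <- sum(case$activity_true$values > 0 & kid$values)
  expect_equal(act_vox, full)  # all mask voxels are hot
  # the cold pelvis exists: hot kidney voxels < raw ellipsoid voxel count
  cfg <- phantom_config()
  o <- cfg$organs$kidney_right
  raw <- sum(voxdosim:::rasterize_ellipsoid(cfg$shape, cfg$spacing_mm,
                                            o$center, o$semi))
  expect_lt(full, raw)
})

test_that("spect simulation calibrates counts and conserves blurred mass", {
  cal <- calibration_config(ccf = 9.64, psf_fwhm_mm = 15)
  sp <- c(4, 4, 4)
  act <- array(0, c(21, 21, 21)); act[11, 11, 11] <- 1  # 1 MBq point source
  activity <- volume_grid(act, sp, "MBq")

  # blur on, Poisson off: total counts conserved within 1% (edge loss only)
  counts <- simulate_spect(activity, cal, poisson = FALSE)
  expect_equal(sum(counts$values), 9.64, tolerance = 0.01)

  # blur off, Poisson off: exact calibration identity
  cal0 <- calibration_config(ccf = 9.64, psf_fwhm_mm = 0)
  counts0 <- simulate_spect(activity, cal0, poisson = FALSE)
  expect_identical(counts0$values, act * 9.64)

  # calibration inverse recovers activity exactly
  back <- counts_to_activity(counts0, cal0)
  expect_identical(back$values, act)
  expect_identical(back$quantity, "MBq")

  # zero activity gives zero counts even with noise on
  zero <- volume_grid(array(0, c(5, 5, 5)), sp, "MBq")
  expect_true(all(simulate_spect(zero, cal, seed = 3)$values == 0))

  # Poisson draw is seeded
  n1 <- simulate_spect(activity, cal, seed = 5)
  n2 <- simulate_spect(activity, cal, seed = 5)
  expect_identical(n1$values, n2$values)

  neg <- volume_grid(array(-1, c(3, 3, 3)), sp, "MBq")
  expect_error(simulate_spect(neg, cal), class = "voxdosim_format_error")
})

test_that("contour perturbation is seeded, identity at sigma 0, monotone in sigma", {
  sph <- sphere_mask(30, c(2, 2, 2))

  same <- perturb_contour(sph, 0, seed = 1)
  expect_identical(same$values, sph$values)
  expect_equal(dice(same, sph), 1.0)

  p1 <- perturb_contour(sph, 2, seed = 9)
  p2 <- perturb_contour(sph, 2, seed = 9)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values, perturb_contour(sph, 2, seed = 10)$values))

  expect_error(perturb_contour(sph, -1), class = "voxdosim_format_error")

  # over seeds, agreement degrades monotonically with sigma
  mean_dsc <- function(sigma) {
    mean(vapply(1:20, function(s)
      dice(perturb_contour(sph, sigma, seed = s), sph), numeric(1)))
  }
  d1 <- mean_dsc(1); d4 <- mean_dsc(4)
  expect_gt(d1, d4)
})

test_that("gross failures behave geometrically", {
  sph <- sphere_mask(40, c(2, 2, 2))

  expect_identical(inject_gross_failure(sph, "truncate_plane", 0)$values,
                   sph$values)

  # truncating a 40 mm sphere 35 mm deep moves the far pole >= 30 mm
  tr <- inject_gross_failure(sph, "truncate_plane", 35, seed = 4)
  expect_gte(hausdorff(tr, sph), 30)

  tr2 <- inject_gross_failure(sph, "truncate_plane", 35, seed = 4)
  expect_identical(tr$values, tr2$values)

  expect_error(inject_gross_failure(sph, "truncate_plane", 1000, seed = 1),
               class = "voxdosim_empty_result_error")

  # bleeding grows the mask toward the neighbour by ~magnitude
  a <- sphere_mask(12, c(2, 2, 2), margin_vox = 12)
  nb_vals <- array(FALSE, dim(a$values)); nb_vals[dim(a$values)[1], 1, 1] <- TRUE
  nb <- organ_mask(nb_vals, a$spacing, "liver")
  bled <- inject_gross_failure(a, "bleed_into_neighbor", 10, seed = 2,
                               neighbor = nb)
  expect_gt(sum(bled$values), sum(a$values))
  expect_true(all(bled$values[a$values]))  # original mask retained
  expect_equal(hausdorff(bled, a), 10, tolerance = 0.25)
})

test_that("cohorts are reproducible with the documented seed derivation", {
  cfg <- small_phantom_config()
  co1 <- generate_cohort(cfg, 6, seed = 3)
  co2 <- generate_cohort(cfg, 6, seed = 3)
  expect_identical(sapply(co1, function(c) c$meta$spleen_absent),
                   sapply(co2, function(c) c$meta$spleen_absent))
  expect_identical(co1[[2]]$counts$values, co2[[2]]$counts$values)
  expect_identical(co1[[4]]$observer_masks$liver$ai$values,
                   co2[[4]]$observer_masks$liver$ai$values)

  # structural contract: 4 manual + 1 ai mask per present organ
  one <- generate_cohort(cfg, 1, seed = 5)[[1]]
  for (organ in names(one$observer_masks)) {
    expect_length(one$observer_masks[[organ]]$manual, 4)
    expect_s3_class(one$observer_masks[[organ]]$ai, "organ_mask")
    expect_identical(one$observer_masks[[organ]]$ai$source, "ai")
  }
  expect_equal(one$timing$t_hours, 24.49)
})

test_that("without hepatomegaly no case shows a gross liver failure", {
  cfg <- small_phantom_config(hepatomegaly_prob = 0, sigma_ai_mm = 2)
  cohort <- generate_cohort(cfg, 8, seed = 11)
  hd_ai <- vapply(cohort, function(case)
    hausdorff(case$observer_masks$liver$ai, case$masks$liver), numeric(1))
  expect_true(all(hd_ai <= 30))
  expect_true(all(vapply(cohort, function(c)
    length(c$meta$gross_failures) == 0, logical(1))))
})

test_that("small perturbations leave the organ mean dose nearly unchanged", {
  # uniform dose inside a 30 mm sphere, sigma <= 1 mm contours
  sph <- sphere_mask(30, c(2, 2, 2))
  dose_vals <- array(0, dim(sph$values))
  dose_vals[sph$values] <- 2
  # smooth dose falloff outside so the perturbed mask sees gradients
  dose_vals <- voxdosim:::blur_array(dose_vals, sph$spacing, 8)
  dose <- volume_grid(dose_vals, sph$spacing, "Gy")
  ref <- dose_stats(dose, sph)$d_mean
  for (s in 1:8) {
    p <- perturb_contour(sph, 1, seed = s)
    expect_lt(abs(dose_stats(dose, p)$d_mean - ref) / ref, 0.02)
  }
})
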