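## Seeded synthetic phantom cases and cohorts. Organs are ellipsoids on a
## common SPECT-resolution grid; realism is not the goal — the generator
## reproduces the *statistical structure* a contour-evaluation and
## single-time-point dosimetry study assumes: organ geometry with a cold
## renal pelvis, liver lesions, occasional hepatomegaly and missing spleens,
## SPECT-like blur + Poisson counts, smooth inter-observer contour
## variability and rare gross segmentation failures.

#' Phantom and cohort configuration
#'
#' Geometry is expressed in mm relative to the grid centre, axis order
#' (slice, row, column). All defaults are the package's documented study
#' conditions; see the methods vignette for the reasoning behind each.
#'
#' @param shape grid extent in voxels per axis.
#' @param spacing_mm voxel size in mm per axis.
#' @param organs named list (liver, spleen, kidney_right, kidney_left) of
#'   lists with `center` (mm), `semi` (semi-axes, mm), `hu` and
#'   `conc_mbq_ml` (activity concentration).
#' @param body list with `center`, `semi`, `hu` for the body ellipsoid.
#' @param air_hu CT value outside the body.
#' @param lesion_count_range integer range of liver lesions per case.
#' @param lesion_radius_range_mm lesion radius range, mm.
#' @param lesion_hu,lesion_conc_multiplier lesion CT value and activity
#'   concentration multiplier relative to liver.
#' @param pelvis_semi_mm,pelvis_offset_mm renal-pelvis exclusion ellipsoid
#'   semi-axes and medial offset (applied mirrored for the two kidneys).
#' @param hepatomegaly per-case flag: enlarge the liver.
#' @param hepatomegaly_factor isotropic liver enlargement factor when
#'   `hepatomegaly` is set.
#' @param hepatomegaly_prob cohort probability of hepatomegaly (drives the
#'   gross-failure rate; default 3/23).
#' @param spleen_absent per-case flag: spleen surgically removed.
#' @param spleen_absent_prob cohort probability of an absent spleen
#'   (default 6/23).
#' @param spleen_failure_prob probability that a hepatomegaly case also has
#'   a gross AI spleen failure (default 2/3, giving ~2 of 23 cases).
#' @param sigma_manual_mm,sigma_ai_mm RMS displacement of the smooth
#'   contour perturbation for manual-like and AI-like observers.
#' @param n_manual_observers manual observers per case.
#' @param gross_failure_magnitude_mm range of the gross-failure magnitude.
#' @param uptake_sdlog,organ_sdlog log-normal spread of the per-case global
#'   and per-organ uptake multipliers.
#' @param t_hours imaging time after administration (cohort default fixed
#'   at 24.49 h).
#' @param t_eff_hours named per-organ effective half-lives (h), used for
#'   bias analysis only.
#' @param acquisition_s effective counting time used to scale Poisson noise.
#' @param calibration a [calibration_config()].
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(
    shape = c(48, 64, 64),
    spacing_mm = c(4.8, 4.8, 4.8),
    organs = list(
      liver        = list(center = c(-25, -25, -55), semi = c(45, 48, 48),
                          hu = 60, conc_mbq_ml = 0.85),
      spleen       = list(center = c(-25, -5, 75),  semi = c(32, 20, 20),
                          hu = 50, conc_mbq_ml = 0.43),
      kidney_right = list(center = c(55, 30, -48),  semi = c(40, 22, 18),
                          hu = 35, conc_mbq_ml = 0.62),
      kidney_left  = list(center = c(55, 30, 48),   semi = c(40, 22, 18),
                          hu = 35, conc_mbq_ml = 0.62)),
    body = list(center = c(0, 0, 0), semi = c(110, 112, 130), hu = 40),
    air_hu = -1000,
    lesion_count_range = c(0L, 3L),
    lesion_radius_range_mm = c(6, 15),
    lesion_hu = 45,
    lesion_conc_multiplier = 2.5,
    pelvis_semi_mm = c(12, 7, 7),
    pelvis_offset_mm = 6,
    hepatomegaly = FALSE,
    hepatomegaly_factor = 1.25,
    hepatomegaly_prob = 3 / 23,
    spleen_absent = FALSE,
    spleen_absent_prob = 6 / 23,
    spleen_failure_prob = 2 / 3,
    sigma_manual_mm = 3,
    sigma_ai_mm = 1,
    n_manual_observers = 4L,
    gross_failure_magnitude_mm = c(35, 50),
    uptake_sdlog = 0.35,
    organ_sdlog = 0.15,
    t_hours = 24.49,
    t_eff_hours = c(liver = 67, spleen = 68, kidney_right = 51,
                    kidney_left = 51),
    acquisition_s = 720,
    calibration = calibration_config()) {
  # coerce list-shaped inputs (e.g. from YAML/JSON configs) to numeric
  shape <- as.integer(unlist(shape))
  spacing_mm <- as.numeric(unlist(spacing_mm))
  organs <- lapply(organs, function(o)
    list(center = as.numeric(unlist(o$center)),
         semi = as.numeric(unlist(o$semi)),
         hu = as.numeric(o$hu), conc_mbq_ml = as.numeric(o$conc_mbq_ml)))
  body <- list(center = as.numeric(unlist(body$center)),
               semi = as.numeric(unlist(body$semi)),
               hu = as.numeric(body$hu))
  lesion_count_range <- as.integer(unlist(lesion_count_range))
  lesion_radius_range_mm <- as.numeric(unlist(lesion_radius_range_mm))
  pelvis_semi_mm <- as.numeric(unlist(pelvis_semi_mm))
  gross_failure_magnitude_mm <- as.numeric(unlist(gross_failure_magnitude_mm))
  t_eff_hours <- unlist(t_eff_hours)
  if (is.null(names(t_eff_hours)))  # e.g. round-tripped through YAML
    names(t_eff_hours) <- VOX_ORGANS[seq_along(t_eff_hours)]
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            all(vapply(organs, function(o) all(o$semi > 0), logical(1))),
            hepatomegaly_factor >= 1,
            hepatomegaly_prob >= 0, hepatomegaly_prob <= 1,
            spleen_absent_prob >= 0, spleen_absent_prob <= 1,
            spleen_failure_prob >= 0, spleen_failure_prob <= 1,
            sigma_manual_mm >= 0, sigma_ai_mm >= 0,
            inherits(calibration, "calibration_config"))
  structure(as.list(environment()), class = "phantom_config")
}

## mm coordinates of voxel centres along one axis, origin at grid centre
axis_coords <- function(n, spacing) (seq_len(n) - 1 - (n - 1) / 2) * spacing

## logical array: voxel centres inside an ellipsoid (centre/semi in mm
## relative to the grid centre)
rasterize_ellipsoid <- function(shape, spacing, center, semi) {
  z2 <- ((axis_coords(shape[1], spacing[1]) - center[1]) / semi[1])^2
  y2 <- ((axis_coords(shape[2], spacing[2]) - center[2]) / semi[2])^2
  x2 <- ((axis_coords(shape[3], spacing[3]) - center[3]) / semi[3])^2
  outer(outer(z2, y2, `+`), x2, `+`) < 1
}

## ---- phantom construction ------------------------------------------------

#' Build one phantom case (CT, true activity, reference masks)
#'
#' Deterministic given `(config, seed)`. CT voxels take the organ HU inside
#' each organ, the body HU elsewhere inside the body ellipsoid and the air
#' HU outside. Activity is concentration x voxel volume inside each organ;
#' liver lesions override the liver concentration; the renal pelvis is cold
#' (zero activity) and excluded from the kidney reference masks.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for lesion placement.
#' @return an object of class `phantom_case` with elements `ct`,
#'   `activity_true`, `masks` (reference [organ_mask()]s), `timing`,
#'   `meta` and `config`.
#' @export
build_phantom <- function(config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- as.integer(config$shape); sp <- config$spacing_mm
  voxel_ml <- prod(sp) / 1000

  organs <- config$organs
  if (config$hepatomegaly)
    organs$liver$semi <- organs$liver$semi * config$hepatomegaly_factor
  if (config$spleen_absent) organs$spleen <- NULL

  half_extent <- (shape - 1) / 2 * sp
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (any(abs(o$center) + o$semi > half_extent + sp / 2))
      vox_stop("voxdosim_construction_error",
               paste0("organ '", nm, "' does not fit inside the grid"))
  }

  organ_vox <- lapply(organs, function(o)
    rasterize_ellipsoid(shape, sp, o$center, o$semi))

  nms <- names(organ_vox)
  if (length(nms) > 1) {
    for (i in seq_len(length(nms) - 1)) for (j in seq(i + 1, length(nms))) {
      if (any(organ_vox[[i]] & organ_vox[[j]]))
        vox_stop("voxdosim_construction_error",
                 paste0("organ ellipsoids overlap: ", nms[i], " and ", nms[j]))
    }
  }

  body <- rasterize_ellipsoid(shape, sp, config$body$center, config$body$semi)

  ct <- array(config$air_hu, shape)
  ct[body] <- config$body$hu
  act <- array(0, shape)
  for (nm in nms) {
    ct[organ_vox[[nm]]] <- organs[[nm]]$hu
    act[organ_vox[[nm]]] <- organs[[nm]]$conc_mbq_ml * voxel_ml
  }

  # liver lesions: seeded spheres well inside the liver ellipsoid
  lesions <- list()
  if (!is.null(organ_vox$liver) && diff(config$lesion_count_range) >= 0) {
    lesions <- with_seed(seed, {
      n_les <- sample(seq(config$lesion_count_range[1],
                          config$lesion_count_range[2]), 1)
      if (n_les > 0) lapply(seq_len(n_les), function(i) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rad_frac <- runif(1)^(1 / 3) * 0.6
        list(center = organs$liver$center + u * rad_frac * organs$liver$semi,
             radius = runif(1, config$lesion_radius_range_mm[1],
                            config$lesion_radius_range_mm[2]))
      }) else list()
    })
    for (les in lesions) {
      inside <- rasterize_ellipsoid(shape, sp, les$center, rep(les$radius, 3)) &
        organ_vox$liver
      ct[inside] <- config$lesion_hu
      act[inside] <- organs$liver$conc_mbq_ml *
        config$lesion_conc_multiplier * voxel_ml
    }
  }

  # cold renal pelvis: zero activity, excluded from the reference mask
  ref_masks <- organ_vox
  for (nm in intersect(c("kidney_right", "kidney_left"), nms)) {
    medial <- if (nm == "kidney_right") 1 else -1
    pelvis <- rasterize_ellipsoid(
      shape, sp,
      organs[[nm]]$center + c(0, 0, medial * config$pelvis_offset_mm),
      config$pelvis_semi_mm)
    act[pelvis & organ_vox[[nm]]] <- 0
    ref_masks[[nm]] <- organ_vox[[nm]] & !pelvis
  }

  masks <- lapply(VOX_ORGANS, function(nm) {
    if (is.null(ref_masks[[nm]]))
      organ_mask(array(FALSE, shape), sp, nm, "reference", absent = TRUE)
    else organ_mask(ref_masks[[nm]], sp, nm, "reference")
  })
  names(masks) <- VOX_ORGANS

  structure(list(
    ct = volume_grid(ct, sp, "HU"),
    activity_true = volume_grid(act, sp, "MBq"),
    masks = masks,
    timing = timing_params(config$t_hours,
                           t_eff_hours = unname(config$t_eff_hours["liver"])),
    meta = list(seed = seed, hepatomegaly = config$hepatomegaly,
                spleen_absent = config$spleen_absent,
                n_lesions = length(lesions), lesions = lesions),
    config = config), class = "phantom_case")
}

## ---- SPECT degradation ---------------------------------------------------

gaussian_taps <- function(fwhm_mm, spacing) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / spacing))
  x <- (-half:half) * spacing
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

## separable Gaussian blur, zero padded at the lattice edge
blur_array <- function(values, spacing, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  d <- dim(values)
  out <- values
  for (ax in 1:3) {
    taps <- gaussian_taps(fwhm_mm, spacing[ax])
    kd <- c(1L, 1L, 1L); kd[ax] <- length(taps)
    out <- array(conv3d_zero(out, d, array(taps, kd), kd), d)
  }
  out
}

#' Simulate a SPECT-like count-rate map from a true activity map
#'
#' Expected count rate is `activity x ccf`, blurred by an isotropic
#' Gaussian of FWHM `psf_fwhm_mm` (the effective post-reconstruction system
#' resolution), then optionally Poisson-resampled assuming an effective
#' counting time of `acquisition_s` seconds. Blurring conserves total
#' expected counts for interior sources (zero padding loses only edge
#' spill).
#'
#' @param activity a [volume_grid()] tagged `MBq`, non-negative.
#' @param cal a [calibration_config()] (supplies `ccf` and `psf_fwhm_mm`).
#' @param seed integer seed for the Poisson draw.
#' @param poisson logical; disable to get the noise-free expectation.
#' @param acquisition_s effective counting time in seconds.
#' @return a [volume_grid()] tagged `cps`.
#' @export
simulate_spect <- function(activity, cal, seed = 1L, poisson = TRUE,
                           acquisition_s = 720) {
  stopifnot(inherits(activity, "volume_grid"),
            inherits(cal, "calibration_config"))
  if (activity$quantity != "MBq")
    stop_format("simulate_spect needs an activity map tagged 'MBq', got '",
                activity$quantity, "'")
  if (any(activity$values < 0))
    stop_format("activity map contains negative values")
  expected <- blur_array(activity$values * cal$ccf, activity$spacing,
                         cal$psf_fwhm_mm)
  if (poisson) {
    stopifnot(acquisition_s > 0)
    counts <- with_seed(seed,
      rpois(length(expected), expected * acquisition_s)) / acquisition_s
    expected <- array(counts, dim(expected))
  }
  volume_grid(expected, activity$spacing, "cps")
}

## ---- contour perturbation ------------------------------------------------

#' Perturb a contour with a smooth random displacement field
#'
#' Emulates inter-observer contouring variability: the mask is warped by a
#' spatially smooth, seeded random vector field of RMS magnitude
#' `sigma_mm`. The warp resamples the binary mask trilinearly and
#' re-thresholds at 0.5, so agreement metrics vary continuously with
#' `sigma_mm`. Deterministic given `(mask, sigma_mm, seed)`. Topology is
#' not guaranteed.
#'
#' @param mask a non-empty [organ_mask()].
#' @param sigma_mm RMS displacement magnitude, mm (>= 0).
#' @param seed integer seed.
#' @param corr_fwhm_mm spatial correlation length (FWHM of the smoothing
#'   applied to the white-noise field), mm.
#' @param source source label for the returned mask.
#' @return a perturbed [organ_mask()].
#' @export
perturb_contour <- function(mask, sigma_mm, seed = 1L, corr_fwhm_mm = 12,
                            source = mask$source) {
  stopifnot(inherits(mask, "organ_mask"))
  if (sigma_mm < 0) stop_format("`sigma_mm` must be >= 0")
  if (!any(mask$values)) stop_metric("cannot perturb an empty mask")
  if (sigma_mm == 0) {
    out <- mask; out$source <- source
    return(out)
  }
  d <- dim(mask$values); sp <- mask$spacing

  # work on the mask bounding box plus a margin wide enough for the warp
  idx <- which(mask$values, arr.ind = TRUE)
  margin <- ceiling((4 * sigma_mm + corr_fwhm_mm) / sp)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(d, apply(idx, 2, max) + margin)
  sub <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)

  disp <- with_seed(seed, lapply(1:3, function(ax) {
    f <- blur_array(array(rnorm(prod(ds)), ds), sp, corr_fwhm_mm)
    f * (sigma_mm / sqrt(3)) / sqrt(mean(f^2))
  }))

  base <- expand.grid(i = seq_len(ds[1]) - 1, j = seq_len(ds[2]) - 1,
                      k = seq_len(ds[3]) - 1)
  warped <- trilinear_sample(
    as.numeric(sub), ds,
    base$i + as.vector(disp[[1]]) / sp[1],
    base$j + as.vector(disp[[2]]) / sp[2],
    base$k + as.vector(disp[[3]]) / sp[3])

  out_vals <- mask$values
  out_vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    array(warped > 0.5, ds)
  organ_mask(out_vals, sp, mask$organ, source)
}

## ---- gross segmentation failures ----------------------------------------

mask_coords_mm <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  sweep(idx - 1, 2, mask$spacing, `*`)
}

#' Inject a gross segmentation failure into a mask
#'
#' Two failure modes observed with automatic segmentation under
#' hepatomegaly: `truncate_plane` removes every voxel deeper than
#' `magnitude_mm` behind a random plane (a large missing-slab error);
#' `bleed_into_neighbor` grows the mask by up to `magnitude_mm` on the side
#' facing a neighbouring organ (contour leaking across an obscured
#' boundary).
#'
#' @param mask a non-empty [organ_mask()].
#' @param mode `"truncate_plane"` or `"bleed_into_neighbor"`.
#' @param magnitude_mm failure magnitude in mm; 0 is the identity.
#' @param seed integer seed (plane orientation).
#' @param neighbor neighbouring [organ_mask()], required for
#'   `bleed_into_neighbor`.
#' @return the damaged [organ_mask()].
#' @export
inject_gross_failure <- function(mask, mode = c("truncate_plane",
                                                "bleed_into_neighbor"),
                                 magnitude_mm, seed = 1L, neighbor = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "organ_mask"), magnitude_mm >= 0)
  if (!any(mask$values)) stop_metric("cannot damage an empty mask")
  if (magnitude_mm == 0) return(mask)
  sp <- mask$spacing

  if (mode == "truncate_plane") {
    nrm <- with_seed(seed, { v <- rnorm(3); v / sqrt(sum(v^2)) })
    coords <- mask_coords_mm(mask)
    proj <- as.vector(coords %*% nrm)
    keep <- proj <= max(proj) - magnitude_mm
    if (!any(keep))
      vox_stop("voxdosim_empty_result_error",
               "truncation magnitude exceeds the mask extent")
    idx <- which(mask$values, arr.ind = TRUE)[keep, , drop = FALSE]
    vals <- array(FALSE, dim(mask$values))
    vals[idx] <- TRUE
    return(organ_mask(vals, sp, mask$organ, mask$source))
  }

  # bleed_into_neighbor
  if (is.null(neighbor) || !any(neighbor$values))
    stop_format("`bleed_into_neighbor` needs a non-empty `neighbor` mask")
  validate_alignment(mask, neighbor)
  bp <- boundary_points(mask)$points
  cen_m <- colMeans(mask_coords_mm(mask))
  cen_n <- colMeans(mask_coords_mm(neighbor))
  u <- cen_n - cen_m; u <- u / sqrt(sum(u^2))

  d <- dim(mask$values)
  idx_all <- which(!mask$values, arr.ind = TRUE)
  coords_all <- sweep(idx_all - 1, 2, sp, `*`)
  toward <- as.vector(sweep(coords_all, 2, cen_m, `-`) %*% u) > 0
  cand_idx <- idx_all[toward, , drop = FALSE]
  cand_xyz <- coords_all[toward, , drop = FALSE]
  near <- nn_dist_sq(cand_xyz, bp) <= magnitude_mm^2
  vals <- mask$values
  vals[cand_idx[near, , drop = FALSE]] <- TRUE
  organ_mask(vals, sp, mask$organ, mask$source)
}

## ---- cohort generation ---------------------------------------------------

#' Generate a seeded synthetic cohort
#'
#' Per-case seeds are derived from the master seed with [derive_seed()], so
#' the cohort is a pure function of `(config, n_cases, seed)`. Each case
#' draws its uptake multipliers, spleen-absence and hepatomegaly status,
#' builds the phantom, simulates a count map, and produces
#' `n_manual_observers` manual-like and one AI-like observer mask per
#' present organ. Hepatomegaly cases get a gross AI liver failure
#' (plane truncation) and, with probability `spleen_failure_prob`, a gross
#' AI spleen failure (bleed toward the liver).
#'
#' @param config a [phantom_config()].
#' @param n_cases number of cases (>= 1); the emulated study has 23.
#' @param seed master integer seed.
#' @return a list of `phantom_case` objects, each extended with `counts`
#'   (cps [volume_grid()]) and `observer_masks` (per organ: `$manual`, a
#'   list, and `$ai`).
#' @export
generate_cohort <- function(config, n_cases = 23, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"), n_cases >= 1)
  lapply(seq_len(n_cases), function(i) {
    case_seed <- derive_seed(seed, i)
    draws <- with_seed(case_seed, list(
      spleen_absent = runif(1) < config$spleen_absent_prob,
      hepatomegaly = runif(1) < config$hepatomegaly_prob,
      global_uptake = rlnorm(1, 0, config$uptake_sdlog),
      organ_uptake = rlnorm(length(config$organs), 0, config$organ_sdlog),
      failure_magnitude = runif(2, config$gross_failure_magnitude_mm[1],
                                config$gross_failure_magnitude_mm[2]),
      spleen_fails = runif(1) < config$spleen_failure_prob))

    cfg <- config
    cfg$spleen_absent <- draws$spleen_absent
    cfg$hepatomegaly <- draws$hepatomegaly
    for (k in seq_along(cfg$organs))
      cfg$organs[[k]]$conc_mbq_ml <- cfg$organs[[k]]$conc_mbq_ml *
        draws$global_uptake * draws$organ_uptake[k]

    case <- build_phantom(cfg, derive_seed(case_seed, 1))
    case$id <- i
    case$counts <- simulate_spect(case$activity_true, cfg$calibration,
                                  seed = derive_seed(case_seed, 2),
                                  acquisition_s = cfg$acquisition_s)

    failures <- list()
    obs <- list()
    for (oi in seq_along(VOX_ORGANS)) {
      organ <- VOX_ORGANS[oi]
      ref <- case$masks[[organ]]
      if (ref$absent) { obs[[organ]] <- NULL; next }
      manual <- lapply(seq_len(cfg$n_manual_observers), function(j)
        perturb_contour(ref, cfg$sigma_manual_mm,
                        seed = derive_seed(case_seed, 100 + 10 * oi + j),
                        source = "manual"))
      ai <- perturb_contour(ref, cfg$sigma_ai_mm,
                            seed = derive_seed(case_seed, 200 + oi),
                            source = "ai")
      if (draws$hepatomegaly && organ == "liver") {
        ai <- inject_gross_failure(ai, "truncate_plane",
                                   draws$failure_magnitude[1],
                                   seed = derive_seed(case_seed, 300))
        failures$liver <- TRUE
      }
      if (draws$hepatomegaly && draws$spleen_fails && organ == "spleen") {
        ai <- inject_gross_failure(ai, "bleed_into_neighbor",
                                   draws$failure_magnitude[2],
                                   seed = derive_seed(case_seed, 301),
                                   neighbor = case$masks$liver)
        failures$spleen <- TRUE
      }
      obs[[organ]] <- list(manual = manual, ai = ai)
    }
    case$observer_masks <- obs
    case$meta$spleen_absent <- draws$spleen_absent
    case$meta$hepatomegaly <- draws$hepatomegaly
    case$meta$gross_failures <- names(failures)
    case
  })
}
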