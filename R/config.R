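## Configuration records: scanner calibration, CT-density conversion,
## imaging-time parameters and contour tolerance criteria.

#' CT value to mass-density conversion table
#'
#' Ordered (HU, g/cm3) pairs, strictly increasing in HU, used for
#' piecewise-linear interpolation with clamping beyond the table ends. The
#' table must anchor water: an entry mapping HU 0 to 1.0 g/cm3.
#'
#' @param hu numeric vector of Hounsfield units, strictly increasing.
#' @param density matching mass densities in g/cm3, all >= 0.
#' @return an object of class `density_table`.
#' @export
density_table <- function(hu, density) {
  hu <- as.numeric(hu); density <- as.numeric(density)
  if (length(hu) < 2L || length(hu) != length(density))
    stop_format("density table needs >= 2 matched (HU, density) pairs")
  if (any(diff(hu) <= 0))
    stop_format("density table HU values must be strictly increasing")
  if (any(density < 0))
    stop_format("densities must be non-negative")
  w <- which(hu == 0)
  if (length(w) != 1L || abs(density[w] - 1.0) > 1e-9)
    stop_format("density table must contain the water anchor (HU 0, 1.0 g/cm3)")
  structure(list(hu = hu, density = density), class = "density_table")
}

#' Default tissue-characterisation density table
#'
#' A typical CT-to-density calibration of the kind measured on a tissue
#' characterisation phantom: air, lung, adipose, water, soft tissue and
#' bone anchors.
#'
#' @return a [density_table()].
#' @export
default_density_table <- function() {
  density_table(
    hu      = c(-1000, -700, -98,    0,    60,  1000, 3000),
    density = c(0.00121, 0.30, 0.93, 1.00, 1.06, 1.60, 2.70))
}

#' Scanner calibration configuration
#'
#' @param ccf cross-calibration factor in cps/MBq (count rate per unit
#'   activity, measured on a uniform phantom of known activity); e.g. 9.64
#'   for a Symbia T6 and 9.92 for a Symbia T16.
#' @param density_table a [density_table()].
#' @param psf_fwhm_mm effective isotropic system blur used when simulating
#'   SPECT-like count maps, mm FWHM.
#' @return an object of class `calibration_config`.
#' @export
calibration_config <- function(ccf = 9.64,
                               density_table = default_density_table(),
                               psf_fwhm_mm = 15) {
  if (!is.numeric(ccf) || length(ccf) != 1L || ccf <= 0)
    stop_format("`ccf` must be a single positive cps/MBq value")
  stopifnot(inherits(density_table, "density_table"), psf_fwhm_mm >= 0)
  structure(list(ccf = ccf, density_table = density_table,
                 psf_fwhm_mm = psf_fwhm_mm),
            class = "calibration_config")
}

#' Imaging-time parameters
#'
#' @param t_hours imaging time after administration, hours (> 0); the
#'   cohort median in the emulated study setting is 24.49 h.
#' @param t_eff_hours organ effective half-life in hours (> 0), used only
#'   for bias analysis — the single-time-point dose estimate itself needs no
#'   half-life.
#' @return an object of class `timing_params` with the derived decay
#'   constant `lambda_eff = log(2) / t_eff_hours` (1/h).
#' @export
timing_params <- function(t_hours = 24.49, t_eff_hours = 67) {
  stopifnot(is.numeric(t_hours), length(t_hours) == 1L, t_hours > 0,
            is.numeric(t_eff_hours), length(t_eff_hours) == 1L,
            t_eff_hours > 0)
  structure(list(t_hours = t_hours, t_eff_hours = t_eff_hours,
                 lambda_eff = log(2) / t_eff_hours),
            class = "timing_params")
}

#' Contour tolerance criteria
#'
#' Defaults follow common practice for organ segmentation acceptance:
#' Dice similarity coefficient at least 0.800 and Hausdorff distance / mean
#' distance to agreement at most 3.0 mm.
#'
#' @param dsc_min minimum acceptable DSC, in (0, 1].
#' @param hd_max_mm maximum acceptable Hausdorff distance, mm.
#' @param mda_max_mm maximum acceptable mean distance to agreement, mm.
#' @return an object of class `tolerance_criteria`.
#' @export
tolerance_criteria <- function(dsc_min = 0.800, hd_max_mm = 3.0,
                               mda_max_mm = 3.0) {
  stopifnot(dsc_min > 0, dsc_min <= 1, hd_max_mm > 0, mda_max_mm > 0)
  structure(list(dsc_min = dsc_min, hd_max_mm = hd_max_mm,
                 mda_max_mm = mda_max_mm),
            class = "tolerance_criteria")
}
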