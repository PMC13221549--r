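## End-to-end orchestration: simulate -> evaluate -> dose -> report, with
## plain-file handoff (CSV/JSON, optionally NIfTI) and a hash manifest so
## identical config + seed give identical artifacts.

stage_error <- function(stage, parent) {
  vox_stop("voxdosim_stage_error",
           paste0("stage '", stage, "' failed: ", conditionMessage(parent)),
           stage = stage)
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    if (inherits(e, "voxdosim_stage_error")) stop(e)
    stage_error(stage, e)
  })
}

#' Run the full phantom-study pipeline
#'
#' Generates a seeded synthetic cohort, evaluates every observer contour,
#' computes single-time-point voxel doses, and writes the cohort report.
#' Artifacts are plain files under `out_dir` (`metrics.csv`, `dose.csv`,
#' `report_*.csv`, `run_config.json`, optionally per-case NIfTI volumes)
#' plus `manifest.json` listing every output with its MD5 hash; identical
#' `config` + `seed` reproduce identical hashes. Any stage failure aborts
#' with a stage-named error (condition class `voxdosim_stage_error`).
#'
#' @param config a named list, or path to a YAML/JSON file, with any of:
#'   `n_cases` (default 23), `seed` (default 1), `out_dir` (required),
#'   `kernel` (path to a kernel file, or `"test"` for
#'   [make_test_kernel()]), `self_fraction`, `range_mm` (test-kernel
#'   parameters), `write_volumes` (default `FALSE`), `density_correction`
#'   (default `FALSE`), `phantom` (named overrides passed to
#'   [phantom_config()]), `criteria` (overrides for [tolerance_criteria()]).
#' @return invisibly, a list with the `manifest` (named MD5 vector), the
#'   `report`, and the metric/dose data frames.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  n_cases <- if (is.null(config$n_cases)) 23L else as.integer(config$n_cases)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stopifnot(seed >= 0)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pcfg <- do.call(phantom_config,
                  if (is.null(config$phantom)) list() else config$phantom)
  criteria <- do.call(tolerance_criteria,
                      if (is.null(config$criteria)) list()
                      else config$criteria)

  message("voxdosim pipeline: ", n_cases, " cases, seed ", seed,
          " -> ", out_dir)

  cohort <- run_stage("simulate", generate_cohort(pcfg, n_cases, seed))
  if (isTRUE(config$write_volumes)) {
    run_stage("simulate", for (case in cohort) {
      stub <- file.path(out_dir, sprintf("case%02d", case$id))
      write_volume(case$ct, paste0(stub, "_ct.nii"))
      write_volume(case$counts, paste0(stub, "_counts.nii"))
      for (organ in names(case$observer_masks))
        write_mask(case$masks[[organ]], paste0(stub, "_", organ, "_ref.nii"))
    })
  }

  metrics <- run_stage("evaluate", evaluate_cohort(cohort, criteria))

  doses <- run_stage("dose", {
    kernel_spec <- if (is.null(config$kernel)) "test" else config$kernel
    kernel <- if (identical(kernel_spec, "test")) {
      make_test_kernel(
        pcfg$spacing_mm,
        self_fraction = if (is.null(config$self_fraction)) 0.9
                        else config$self_fraction,
        range_mm = if (is.null(config$range_mm)) 5 else config$range_mm)
    } else load_kernel(kernel_spec)
    dose_cohort(cohort, kernel, pcfg$calibration,
                density_correction = isTRUE(config$density_correction))
  })

  report <- run_stage("report", build_report(metrics, doses))

  files <- c(metrics = "metrics.csv", dose = "dose.csv",
             accuracy = "report_accuracy.csv",
             rates = "report_criteria_rates.csv",
             dose_report = "report_dose.csv")
  write.csv(metrics, file.path(out_dir, files["metrics"]), row.names = FALSE)
  write.csv(doses, file.path(out_dir, files["dose"]), row.names = FALSE)
  write.csv(report$accuracy, file.path(out_dir, files["accuracy"]),
            row.names = FALSE)
  write.csv(report$criteria_rates, file.path(out_dir, files["rates"]),
            row.names = FALSE)
  write.csv(report$dose, file.path(out_dir, files["dose_report"]),
            row.names = FALSE)
  cfg_echo <- config
  cfg_echo$n_cases <- n_cases; cfg_echo$seed <- seed
  jsonlite::write_json(cfg_echo, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # run_config.json echoes absolute paths, so it is listed but not hashed
  outputs <- setdiff(list.files(out_dir, recursive = TRUE),
                     c("manifest.json", "run_config.json"))
  manifest <- tools::md5sum(file.path(out_dir, sort(outputs)))
  names(manifest) <- sort(outputs)
  jsonlite::write_json(as.list(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(manifest = manifest, report = report,
                 metrics = metrics, doses = doses))
}
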