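## Cohort-level evaluation: per-case contour metrics and organ dose
## statistics, assembled into accuracy and dose report tables
## (median (IQR), criteria rates, paired Wilcoxon p-values).

#' Contour metrics for every observer mask of a cohort
#'
#' Evaluates every manual and AI observer mask of every case against the
#' case's reference masks. Absent organs are skipped (not errors).
#'
#' @param cohort list of cases from [generate_cohort()].
#' @param criteria a [tolerance_criteria()].
#' @return a data frame with one row per (case, organ, source, observer):
#'   metrics, pass flags and a `gross_failure` indicator.
#' @export
evaluate_cohort <- function(cohort, criteria = tolerance_criteria()) {
  rows <- list()
  for (case in cohort) {
    for (organ in names(case$observer_masks)) {
      ref <- case$masks[[organ]]
      obs <- case$observer_masks[[organ]]
      cand <- c(obs$manual, list(obs$ai))
      obs_id <- c(seq_along(obs$manual), 1L)
      for (ci in seq_along(cand)) {
        res <- evaluate_contour(cand[[ci]], ref, criteria)
        rows[[length(rows) + 1L]] <- data.frame(
          case = case$id, organ = organ,
          source = cand[[ci]]$source, observer = obs_id[ci],
          dsc = res$dsc, hd_mm = res$hd_mm, mda_mm = res$mda_mm,
          dsc_pass = unname(res$flags["dsc"]),
          hd_pass = unname(res$flags["hd"]),
          mda_pass = unname(res$flags["mda"]),
          gross_failure = cand[[ci]]$source == "ai" &&
            organ %in% case$meta$gross_failures,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Absorbed-dose statistics for every mask of a cohort
#'
#' Runs the single-time-point dose chain once per case (counts -> activity
#' -> voxel S-value convolution -> Hanscheid integration) and extracts
#' [dose_stats()] for the reference and every observer mask.
#'
#' @param cohort list of cases from [generate_cohort()].
#' @param kernel a [dose_kernel()] on the cohort grid.
#' @param cal a [calibration_config()].
#' @param density_correction logical; apply the CT-density mass correction.
#' @return a data frame with one row per (case, organ, source, observer).
#' @export
dose_cohort <- function(cohort, kernel, cal, density_correction = FALSE) {
  rows <- list()
  for (case in cohort) {
    activity <- counts_to_activity(case$counts, cal)
    density <- if (density_correction)
      hu_to_density(case$ct, cal$density_table) else NULL
    rate <- convolve_dose_rate(activity, kernel, density)
    dose <- hanscheid_integrate(rate, case$timing)
    for (organ in names(case$observer_masks)) {
      masks <- c(list(case$masks[[organ]]),
                 case$observer_masks[[organ]]$manual,
                 list(case$observer_masks[[organ]]$ai))
      obs_id <- c(0L, seq_along(case$observer_masks[[organ]]$manual), 1L)
      for (mi in seq_along(masks)) {
        st <- dose_stats(dose, masks[[mi]])
        rows[[length(rows) + 1L]] <- data.frame(
          case = case$id, organ = organ, source = st$source,
          observer = obs_id[mi], d_mean = st$d_mean, d_max = st$d_max,
          d_min = st$d_min, volume_ml = st$volume_ml,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

fmt_miqr <- function(x) {
  q <- median_iqr(x)
  sprintf("%.3g (%.3g-%.3g)", q["median"], q["q1"], q["q3"])
}

## per-case mean over manual observers, used for paired tests so each case
## contributes one manual value (the cohort design has 4 manual observers)
case_means <- function(df, value) {
  agg <- aggregate(df[[value]], by = list(case = df$case), FUN = mean)
  agg$x[order(agg$case)]
}

#' Assemble cohort report tables
#'
#' Builds the accuracy table (per organ x metric: manual and AI median
#' (IQR), paired Wilcoxon p-value, criteria rates) and the dose table (per
#' organ x dose statistic: reference/manual/AI median (IQR), paired
#' p-values against the reference, and the relative difference of medians
#' in percent). Manual entries pool all observer-case records for the
#' summaries; paired tests use the per-case mean of the manual observers so
#' each case contributes one pair. Row order is deterministic.
#'
#' @param metrics data frame from [evaluate_cohort()].
#' @param doses data frame from [dose_cohort()].
#' @return a list of class `cohort_report` with data frames `accuracy`,
#'   `criteria_rates` and `dose`.
#' @export
build_report <- function(metrics, doses) {
  organs <- intersect(VOX_ORGANS, unique(metrics$organ))
  acc_rows <- list(); rate_rows <- list(); dose_rows <- list()

  for (organ in organs) {
    mo <- metrics[metrics$organ == organ & !is.na(metrics$dsc), ]
    man <- mo[mo$source == "manual", ]
    ai <- mo[mo$source == "ai", ]
    for (metric in c("dsc", "hd_mm", "mda_mm")) {
      p <- if (nrow(ai) >= 1 && nrow(man) >= 1) {
        wilcoxon_signed_rank(case_means(man, metric),
                             ai[[metric]][order(ai$case)])$p_value
      } else NA_real_
      acc_rows[[length(acc_rows) + 1L]] <- data.frame(
        organ = organ, metric = sub("_mm$", "", metric),
        manual = fmt_miqr(man[[metric]]), ai = fmt_miqr(ai[[metric]]),
        p_value = p, n = length(unique(mo$case)), stringsAsFactors = FALSE)
      flag <- paste0(sub("_mm$", "", metric), "_pass")
      for (src in c("manual", "ai")) {
        so <- mo[mo$source == src, ]
        rate_rows[[length(rate_rows) + 1L]] <- data.frame(
          organ = organ, metric = sub("_mm$", "", metric), source = src,
          rate = round(100 * sum(so[[flag]]) / nrow(so), 1),
          passing = sum(so[[flag]]), total = nrow(so),
          stringsAsFactors = FALSE)
      }
    }

    do <- doses[doses$organ == organ, ]
    ref <- do[do$source == "reference", ]
    ref <- ref[order(ref$case), ]
    man <- do[do$source == "manual", ]
    ai <- do[do$source == "ai", ]
    ai <- ai[order(ai$case), ]
    for (stat in c("d_mean", "d_max", "d_min")) {
      p_man <- if (nrow(man) >= 1)
        wilcoxon_signed_rank(case_means(man, stat), ref[[stat]])$p_value
      else NA_real_
      p_ai <- if (nrow(ai) >= 1)
        wilcoxon_signed_rank(ai[[stat]], ref[[stat]])$p_value else NA_real_
      med_ai <- median_iqr(ai[[stat]])["median"]
      med_ref <- median_iqr(ref[[stat]])["median"]
      dose_rows[[length(dose_rows) + 1L]] <- data.frame(
        organ = organ, stat = stat,
        manual = fmt_miqr(man[[stat]]), ai = fmt_miqr(ai[[stat]]),
        reference = fmt_miqr(ref[[stat]]),
        p_manual = p_man, p_ai = p_ai,
        ai_rel_diff_pct = round(relative_difference(med_ai, med_ref), 1),
        n = nrow(ref), stringsAsFactors = FALSE)
    }
  }

  structure(list(accuracy = do.call(rbind, acc_rows),
                 criteria_rates = do.call(rbind, rate_rows),
                 dose = do.call(rbind, dose_rows)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== Contouring accuracy ==\n"); print(x$accuracy)
  cat("\n== Criteria rates ==\n"); print(x$criteria_rates)
  cat("\n== Absorbed dose ==\n"); print(x$dose)
  invisible(x)
}
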