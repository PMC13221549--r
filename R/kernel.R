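## Voxel S-value dose kernels: small odd-sided 3-D tables of dose rate per
## unit activity in the source voxel (Gy/s per MBq), convolved over an
## activity map to give a dose-rate map (MIRD voxel-level formalism).

#' Construct a voxel S-value dose kernel
#'
#' @param values 3-D array with odd extent on every axis, entries >= 0 in
#'   Gy/s per MBq in the source voxel; the centre entry is the self-dose
#'   term and must be the maximum.
#' @param spacing kernel voxel sizes in mm; must equal the dose grid spacing
#'   at time of use.
#' @return an object of class `dose_kernel`.
#' @export
dose_kernel <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_kernel("kernel must be a 3-D array")
  d <- dim(values)
  if (any(d %% 2L == 0L))
    stop_kernel("kernel extents must all be odd, got ",
                paste(d, collapse = "x"))
  if (any(values < 0) || any(!is.finite(values)))
    stop_kernel("kernel entries must be finite and non-negative")
  ctr <- (d + 1L) %/% 2L
  if (values[ctr[1], ctr[2], ctr[3]] < max(values))
    stop_kernel("kernel centre (self-dose term) must be the maximum entry")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_kernel("kernel `spacing` must be 3 positive mm values")
  structure(list(values = values, spacing = spacing),
            class = "dose_kernel")
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf("<dose_kernel> %s voxels @ %s mm, total %.4g Gy/s per MBq\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

## Kernel file dialect: line 1 is a JSON header
##   {"spacing_mm":[s,r,c],"units":"Gy_s_per_MBq","shape":[a,b,c]}
## followed by the flattened table in row-major order (slice index slowest,
## column index fastest), one comma-separated record per line.

#' Write a dose kernel in the package's text dialect
#'
#' @param kernel a [dose_kernel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  header <- jsonlite::toJSON(
    list(spacing_mm = kernel$spacing, units = "Gy_s_per_MBq",
         shape = dim(kernel$values)),
    auto_unbox = FALSE, digits = NA)
  # row-major flatten: slice slowest, column fastest
  flat <- as.vector(aperm(kernel$values, c(3, 2, 1)))
  body <- vapply(split(flat, rep(seq_len(dim(kernel$values)[1] *
                                           dim(kernel$values)[2]),
                                 each = dim(kernel$values)[3])),
                 function(row) paste(format(row, digits = 17), collapse = ","),
                 character(1))
  writeLines(c(as.character(header), body), path)
  invisible(path)
}

#' Load a dose kernel from the package's text dialect
#'
#' Verifies odd extents, non-negative entries and that the centre entry is
#' the maximum (self-dose dominance).
#'
#' @param path kernel file path.
#' @return a [dose_kernel()].
#' @export
load_kernel <- function(path) {
  if (!file.exists(path)) stop_kernel("no such kernel file: '", path, "'")
  lines <- readLines(path)
  if (length(lines) < 2L) stop_kernel("kernel file '", path, "' is truncated")
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e)
                       stop_kernel("kernel header is not valid JSON: ",
                                   conditionMessage(e)))
  shape <- as.integer(header$shape)
  if (length(shape) != 3L)
    stop_kernel("kernel header must give a 3-axis shape")
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(lines[-1], ",", fixed = TRUE))))
  if (length(vals) != prod(shape) || any(is.na(vals)))
    stop_kernel("kernel body has ", length(vals), " entries, expected ",
                prod(shape))
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  dose_kernel(arr, as.numeric(header$spacing_mm))
}

#' Build a synthetic test kernel with controlled self-dose fraction
#'
#' A stand-in for a database voxel S-value kernel, used by the phantom
#' pipeline and the analytic recovery tests. The centre voxel carries
#' `self_fraction` of the total kernel mass; the remainder decays
#' exponentially with radius over `range_mm` and is truncated at
#' `3 * range_mm`. The default total is the physical absorbed-fraction-one
#' normalisation for the mean beta energy per decay of Lu-177
#' (0.1475 MeV) deposited in a water-density voxel:
#' `total = E * 1.602e-13 J/MeV * 1e6 /s/MBq / (voxel volume cm^3 * 1e-3 kg)`
#' in Gy/s per MBq, so a uniform concentration of 1 MBq/mL yields an
#' interior dose rate of about 2.36e-5 Gy/s regardless of voxel size.
#'
#' @param spacing voxel sizes in mm (slice, row, column).
#' @param self_fraction fraction of kernel mass in the centre voxel, in
#'   (0, 1]; 1 gives a single-entry, purely local-deposition kernel.
#' @param range_mm exponential decay length of the off-centre tail, mm.
#' @param total total kernel mass in Gy/s per MBq; `NULL` uses the physical
#'   default above.
#' @param energy_mev mean energy deposited per decay, MeV (Lu-177 beta
#'   default).
#' @return a [dose_kernel()].
#' @export
#' @examples
#' k <- make_test_kernel(c(4.8, 4.8, 4.8), self_fraction = 0.9, range_mm = 5)
#' sum(k$values)
make_test_kernel <- function(spacing, self_fraction = 0.9, range_mm = 5,
                             total = NULL, energy_mev = 0.1475) {
  stopifnot(self_fraction > 0, self_fraction <= 1, range_mm > 0)
  spacing <- as.numeric(spacing)
  if (is.null(total)) {
    voxel_cm3 <- prod(spacing) / 1000
    total <- energy_mev * 1.602e-13 * 1e6 / (voxel_cm3 * 1e-3)
  }
  if (self_fraction == 1) {
    return(dose_kernel(array(total, c(1, 1, 1)), spacing))
  }
  half <- pmax(1L, as.integer(floor(3 * range_mm / spacing)))
  d <- 2L * half + 1L
  idx <- lapply(1:3, function(ax) (seq_len(d[ax]) - half[ax] - 1) * spacing[ax])
  r <- sqrt(outer(outer(idx[[1]]^2, idx[[2]]^2, `+`), idx[[3]]^2, `+`))
  w <- exp(-r / range_mm)
  w[r > 3 * range_mm] <- 0
  ctr <- half + 1L
  w[ctr[1], ctr[2], ctr[3]] <- 0
  w <- w / sum(w) * (1 - self_fraction) * total
  w[ctr[1], ctr[2], ctr[3]] <- self_fraction * total
  dose_kernel(w, spacing)
}
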