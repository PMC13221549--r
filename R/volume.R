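## Core lattice types: scalar volumes and binary organ masks on a common
## voxel grid. Axis order is fixed as (slice, row, column); the world
## position of a voxel is its centre, with the origin at the centre of voxel
## (1,1,1); spacing is in mm per axis. Mismatched grids are an error, never
## silently resampled.

VOX_QUANTITIES <- c("HU", "cps", "MBq", "Gy_per_s", "Gy", "g_per_cm3")
VOX_ORGANS     <- c("liver", "spleen", "kidney_right", "kidney_left")
VOX_SOURCES    <- c("reference", "manual", "ai")

#' Construct a scalar volume on a 3-D voxel grid
#'
#' A `volume_grid` carries a 3-D numeric lattice, a per-axis physical
#' spacing in mm (slice, row, column order) and an explicit quantity tag,
#' one of `"HU"`, `"cps"`, `"MBq"`, `"Gy_per_s"`, `"Gy"` or `"g_per_cm3"`.
#' Operations check the tag and refuse physically meaningless inputs.
#'
#' @param values 3-D numeric array, all values finite.
#' @param spacing numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param quantity quantity tag.
#' @return an object of class `volume_grid`.
#' @export
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), spacing = c(1.5, 1.37, 1.37),
#'                  quantity = "HU")
#' dim(v$values)
volume_grid <- function(values, spacing, quantity) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_format("`values` must be a 3-D array, got dimensionality ",
                length(dim(values)))
  if (!all(is.finite(values)))
    stop_format("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_format("`spacing` must be 3 positive voxel sizes in mm")
  quantity <- match.arg(quantity, VOX_QUANTITIES)
  structure(list(values = values, spacing = spacing, quantity = quantity),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s, %s voxels, spacing %s mm\n",
              x$quantity, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Construct a binary organ mask
#'
#' A mask is a binary lattice aligned with a companion [volume_grid()],
#' labelled with the organ it delineates and the contouring source that
#' produced it. An all-zero mask is only valid when explicitly flagged
#' `absent` (e.g. spleen removed by surgery).
#'
#' @param values 3-D array coercible to logical (0/1).
#' @param spacing voxel sizes in mm (slice, row, column).
#' @param organ one of `"liver"`, `"spleen"`, `"kidney_right"`,
#'   `"kidney_left"`.
#' @param source one of `"reference"`, `"manual"`, `"ai"`.
#' @param absent logical; `TRUE` marks an organ known to be missing.
#' @return an object of class `organ_mask`.
#' @export
organ_mask <- function(values, spacing, organ, source = "reference",
                       absent = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_format("mask `values` must be a 3-D array")
  storage.mode(values) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_format("`spacing` must be 3 positive voxel sizes in mm")
  organ <- match.arg(organ, VOX_ORGANS)
  source <- match.arg(source, VOX_SOURCES)
  if (!absent && !any(values))
    stop_format("mask for ", organ, " has no foreground voxels; ",
                "flag `absent = TRUE` if the organ is missing")
  structure(list(values = values, spacing = spacing, organ = organ,
                 source = source, absent = isTRUE(absent)),
            class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf("<organ_mask> %s (%s)%s: %d voxels of %s\n",
              x$organ, x$source, if (x$absent) " [absent]" else "",
              sum(x$values), paste(dim(x$values), collapse = "x")))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$values)

#' Check that two lattices share a grid
#'
#' Returns invisibly when the two objects have identical shapes and per-axis
#' spacings agreeing within 1e-6 mm; otherwise raises an alignment error
#' naming the first differing axis. The check is symmetric in its arguments.
#'
#' @param a,b `volume_grid` or `organ_mask` objects.
#' @return `TRUE`, invisibly.
#' @export
validate_alignment <- function(a, b) {
  da <- dim(a$values); db <- dim(b$values)
  for (ax in 1:3) {
    if (da[ax] != db[ax])
      stop_alignment(sprintf(
        "shape mismatch on axis %d: %d vs %d voxels", ax, da[ax], db[ax]))
  }
  for (ax in 1:3) {
    if (abs(a$spacing[ax] - b$spacing[ax]) > 1e-6)
      stop_alignment(sprintf(
        "spacing mismatch on axis %d: %.6g vs %.6g mm",
        ax, a$spacing[ax], b$spacing[ax]))
  }
  invisible(TRUE)
}

## ---- NIfTI + JSON-sidecar I/O -------------------------------------------

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

nifti_to_array <- function(img, path) {
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))  # drop NIfTI header attributes
  d <- dim(arr)
  # tolerate trailing singleton 4th dimension some writers emit
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, dim = d[1:3]); d <- dim(arr)
  }
  if (length(d) != 3L)
    stop_format("'", path, "' is not a 3-D image (", length(d), " dimensions)")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop_format("'", path, "' has non-positive voxel spacing")
  list(values = arr, spacing = as.numeric(sp))
}

#' Read a scalar volume from NIfTI
#'
#' The quantity tag is taken from the JSON sidecar written by
#' [write_volume()] (same path with extension `.json`) or, failing that,
#' from the `quantity` argument.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param quantity quantity tag used when no sidecar is present.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, quantity = NULL) {
  if (!file.exists(path)) stop_format("no such file: '", path, "'")
  raw <- nifti_to_array(RNifti::readNifti(path), path)
  meta <- read_sidecar(path)
  q <- if (!is.null(meta$quantity)) meta$quantity else quantity
  if (is.null(q))
    stop_format("'", path, "' has no sidecar; pass `quantity` explicitly")
  volume_grid(raw$values, raw$spacing, q)
}

#' Write a scalar volume as NIfTI plus JSON sidecar
#'
#' @param volume a [volume_grid()].
#' @param path output `.nii` path (uncompressed NIfTI keeps hashes
#'   deterministic across runs).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(quantity = volume$quantity),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a binary organ mask from NIfTI
#'
#' Voxels are thresholded at 0.5, so probabilistic maps become binary.
#' Organ/source labels come from the sidecar or from the arguments. An
#' all-zero image is accepted with a warning and flagged `absent`.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param organ,source labels used when no sidecar is present.
#' @return an [organ_mask()].
#' @export
read_mask <- function(path, organ = NULL, source = NULL) {
  if (!file.exists(path)) stop_format("no such file: '", path, "'")
  raw <- nifti_to_array(RNifti::readNifti(path), path)
  meta <- read_sidecar(path)
  organ <- if (!is.null(meta$organ)) meta$organ else organ
  source <- if (!is.null(meta$source)) meta$source else
    if (is.null(source)) "reference" else source
  if (is.null(organ))
    stop_format("'", path, "' has no sidecar; pass `organ` explicitly")
  vals <- raw$values > 0.5
  absent <- isTRUE(meta$absent)
  if (!any(vals) && !absent) {
    warning("mask '", path, "' is empty; flagging organ as absent",
            call. = FALSE)
    absent <- TRUE
  }
  organ_mask(array(vals, dim(vals)), raw$spacing, organ, source,
             absent = absent)
}

#' Write an organ mask as 8-bit NIfTI plus JSON sidecar
#'
#' @param mask an [organ_mask()].
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  jsonlite::write_json(
    list(organ = mask$organ, source = mask$source, absent = mask$absent),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}
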