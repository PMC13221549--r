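# Fixtures and independent brute-force oracles. The oracles deliberately
# share nothing with the package implementation: boundary detection is a
# plain triple loop over voxels, and distances are full all-pairs matrices.

sphere_mask <- function(radius_mm, spacing = c(2, 2, 2), organ = "liver",
                        margin_vox = 2) {
  n <- 2 * (ceiling(radius_mm / spacing) + margin_vox) + 1
  ctr <- (n + 1) / 2
  vals <- array(FALSE, n)
  idx <- as.matrix(expand.grid(i = 1:n[1], j = 1:n[2], k = 1:n[3]))
  mm <- sweep(sweep(idx, 2, ctr, `-`), 2, spacing, `*`)
  vals[idx[rowSums(mm^2) < radius_mm^2, ]] <- TRUE
  organ_mask(vals, spacing, organ)
}

# 6-connectivity boundary voxel centres, enumerated voxel by voxel
oracle_boundary <- function(mask) {
  m <- mask$values; d <- dim(m); sp <- mask$spacing
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_boundary <- any(vapply(nb, function(p) {
      any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]
    }, logical(1)))
    if (on_boundary)
      pts <- rbind(pts, (c(i, j, k) - 1) * sp)
  }
  pts
}

oracle_dist_matrix <- function(pa, pb) {
  da <- outer(pa[, 1], pb[, 1], `-`)^2 +
    outer(pa[, 2], pb[, 2], `-`)^2 +
    outer(pa[, 3], pb[, 3], `-`)^2
  sqrt(da)
}

oracle_hd <- function(a, b) {
  pa <- oracle_boundary(a); pb <- oracle_boundary(b)
  dm <- oracle_dist_matrix(pa, pb)
  max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}

oracle_mda <- function(a, b) {
  pa <- oracle_boundary(a); pb <- oracle_boundary(b)
  dm <- oracle_dist_matrix(pa, pb)
  (sum(apply(dm, 1, min)) + sum(apply(dm, 2, min))) / (nrow(pa) + nrow(pb))
}

# random non-empty blob mask on a small lattice
random_mask <- function(shape, spacing, organ = "liver") {
  repeat {
    vals <- array(runif(prod(shape)) < 0.25, shape)
    if (any(vals)) return(organ_mask(vals, spacing, organ))
  }
}

# small phantom configuration used where full study-scale runs would be
# wasteful; geometry scaled to fit a coarse grid
small_phantom_config <- function(...) {
  phantom_config(
    shape = c(24, 32, 32), spacing_mm = c(6, 6, 6),
    organs = list(
      liver        = list(center = c(-12, -12, -28), semi = c(22, 24, 24),
                          hu = 60, conc_mbq_ml = 0.85),
      spleen       = list(center = c(-12, -2, 38),  semi = c(16, 10, 10),
                          hu = 50, conc_mbq_ml = 0.43),
      kidney_right = list(center = c(28, 15, -24),  semi = c(20, 11, 9),
                          hu = 35, conc_mbq_ml = 0.62),
      kidney_left  = list(center = c(28, 15, 24),   semi = c(20, 11, 9),
                          hu = 35, conc_mbq_ml = 0.62)),
    body = list(center = c(0, 0, 0), semi = c(55, 56, 65), hu = 40),
    lesion_radius_range_mm = c(5, 9),
    pelvis_semi_mm = c(7, 4, 4), pelvis_offset_mm = 3,
    gross_failure_magnitude_mm = c(20, 28),
    ...)
}
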