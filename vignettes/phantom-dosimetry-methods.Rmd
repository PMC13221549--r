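---
title: "Methods: contour agreement and single-time-point voxel dosimetry on synthetic phantom cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour agreement and single-time-point voxel dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdosim)
```

## Scope and model

`voxdosim` evaluates how organ contouring variability propagates into
voxel-level absorbed dose in ¹⁷⁷Lu-DOTATATE therapy. The package works
entirely downstream of image reconstruction: its inputs are an
attenuation/scatter-corrected SPECT count-rate map (cps), a CT volume (HU)
and binary organ masks, all on one voxel grid. Three models are chained:

1. **Quantification.** Activity per voxel is `A = C / ccf`, where `C` is
   the voxel count rate and `ccf` the scanner cross-calibration factor in
   cps/MBq measured on a phantom of known activity (defaults 9.64, the
   value typical of a Symbia T6-class system). CT converts to mass density
   by piecewise-linear interpolation through an ordered (HU, g/cm³) table
   anchored at water (0 HU → 1.0 g/cm³), clamped outside the table.
2. **Dose rate.** The MIRD voxel-level formalism: the activity map is
   convolved with a voxel S-value kernel (Gy/s per MBq in the source
   voxel) whose spacing must equal the grid spacing exactly — kernel
   resampling is out of scope, and mismatched grids are an error rather
   than being silently interpolated. Convolution is zero-padded: tissue
   outside the scanned lattice neither receives nor contributes dose, a
   deliberate approximation that is exact for sources away from the
   lattice edge. An optional first-order mass correction divides each
   voxel's dose rate by its relative density; it is off by default because
   commercial engines do not document how the density table enters their
   dose step, and both behaviours are testable.
3. **Time integration.** With a single imaging time point `t`, the
   Hänscheid estimator `D = Ḋ(t)·2t/ln 2` integrates the time-activity
   curve without a per-patient effective half-life. Against a
   monoexponential ground truth with half-life `T` its accuracy is the
   closed form `r = (t/T)·2^(1−t/T)` (`underestimation_ratio()`): exact at
   `t = T`, and within 12% for `t` between 75% and 250% of `T`. Published
   statements of a "10%" accuracy window for this method rest on empirical
   kinetics rather than the pure monoexponential; the package documents
   and asserts only the closed form, which bounds the window at 11.6%.
   At an imaging time of 24.49 h — typical when scanning happens at
   discharge rather than at the recommended 72–96 h — the closed form
   predicts underestimation of about 31% (kidneys, T ≈ 51 h), 43% (liver,
   T ≈ 67 h) and 44% (spleen, T ≈ 68 h). These organ half-lives are
   shipped as configuration defaults, not hard-coded truth.

Units are fixed at the interfaces: mm for spacing and distances, hours at
the timing interface (seconds internally, conversion constant 3600 stated
once), MBq, Gy/s, Gy. Every lattice carries an explicit quantity tag and
operations refuse physically meaningless inputs (e.g. integrating a map
that is not a dose rate).

## Contour metrics

Boundaries are 6-connectivity surface voxels: a mask voxel with at least
one of its six face neighbours outside the mask (out-of-lattice counts as
outside). Metrics operate on the mm coordinates of boundary voxel centres,
with the world origin at the centre of the first voxel — one unambiguous
convention for all distance computations, fully supporting anisotropic
spacing. The Hausdorff distance is the exact 100th-percentile value, not a
95% variant. Whether reference implementations compute these metrics on
voxel sets or sub-voxel surface meshes is generally unstated; voxel-set
semantics are adopted here and validated against an all-pairs brute-force
oracle that shares no code with the implementation (criterion: agreement
to 1e-9 mm on random anisotropic lattices).

"Replace the maximum by a mean" leaves the MDA symmetrisation ambiguous.
The default pools both boundary point sets — the mean of all
`|∂A| + |∂B|` nearest-neighbour distances, weighting each side by its
point count; `mda(..., pooled = FALSE)` gives the unweighted mean of the
two directed means instead. For the collinear 1-voxel vs 3-voxel example
the two readings give 0.75 mm and 0.5 mm respectively.

Comparisons where either mask is empty are errors, not 0 or infinity;
organs flagged absent (e.g. splenectomy) produce skipped records so that
cohort code must drop them explicitly, never silently.

The fast path computes directed nearest-neighbour distances in compiled
code by brute force over boundary point pairs rather than via a Euclidean
distance transform: boundary sets at SPECT-scale grids number a few
thousand points, where the O(N·M) kernel is both faster in practice and
simpler to verify against the oracle.

## The phantom generator: what it emulates

The generator produces the statistical structure an evaluation study
assumes, not anatomical realism. Its defaults are the package's study
conditions:

* **Grid**: 48 × 64 × 64 voxels at 4.8 mm isotropic — a SPECT-resolution
  grid (clinical matrices are 128×128 over a large field of view; the
  post-reconstruction voxel size is configurable because it is rarely
  reported).
* **Organs**: ellipsoids in mm coordinates — liver (semi-axes 45/48/48,
  ~430 mL, containing 0–3 hot spherical lesions of 6–15 mm radius at 2.5×
  liver concentration), spleen (~107 mL), two kidneys (~66 mL each) with
  a cold renal-pelvis ellipsoid excluded from the reference mask and
  carrying no activity (pelvis and vessels are excluded from kidney
  contours in practice). Overlapping organs are a construction error.
* **Cohort structure**: spleen absent with probability 6/23 (splenectomy
  rate of the emulated cohort); hepatomegaly with probability 3/23,
  implemented as isotropic liver enlargement (factor 1.25) — a single
  scaled ellipsoid rather than a two-lobe union, which keeps the geometry
  analytically checkable and is sufficient to drive the failure model.
  Imaging time fixed at 24.49 h. Per-case uptake varies log-normally
  (global sdlog 0.35, per-organ 0.15) so dose IQRs span a realistic
  factor of ~2; baseline concentrations (0.85/0.43/0.62 MBq/mL for
  liver/spleen/kidneys) put reference Dmean on the order of 4 / 1.5 / 2 Gy
  after blur losses.
* **SPECT degradation**: expected counts = activity × ccf, blurred by an
  isotropic Gaussian (default FWHM 15 mm — a typical total
  post-reconstruction SPECT resolution; the 4 mm figure often quoted for
  reconstruction pipelines is only the post-filter), then
  Poisson-resampled with an effective counting time of 720 s. No
  attenuation, scatter or projection-domain modelling: the emulated input
  is an already-corrected reconstruction.
* **Observers**: contour variability is a smooth seeded random
  displacement field (white noise smoothed to a 12 mm correlation length,
  scaled to RMS magnitude σ), applied by trilinear resampling of the
  binary mask with re-thresholding at 0.5 — so DSC/HD/MDA vary
  continuously with σ, which morphological dilation would not give. Four
  manual-like observers use σ = 3 mm and one AI-like observer σ = 1 mm;
  these σ were chosen so cohort medians land in the ranges reported for
  human and U-net observers (manual DSC ≈ 0.91–0.96, MDA ≈ 1.3 mm; AI
  DSC ≈ 1), and are illustrative, not inferential — the generator cannot
  identify real inter-observer fields from summary statistics.
* **Gross failures**: hepatomegaly cases receive a gross AI liver failure
  (random plane truncation, magnitude 35–50 mm) and, with probability
  2/3, a gross AI spleen failure (bleed toward the liver), reproducing
  the observation that automatic segmentation failures (HD > 30 mm)
  cluster in enlarged-liver cases.

Determinism: every generator output is a pure function of (config, seed).
Per-case and per-draw seeds derive from the master seed through a
documented splitmix-style 32-bit hash (`derive_seed()`), so cohorts are
portable across sessions and implementations.

What passing tests on these phantoms do **not** show: performance on real
anatomy (non-ellipsoidal organs, contrast-dependent boundaries), real
U-net failure modes, registration or reconstruction artefacts, or
absolute dosimetric accuracy against Monte-Carlo transport. The cohort
tests establish that the *pipeline* orders and propagates contour quality
correctly, not that any segmentation method is clinically adequate.

## Statistics

Summaries are median (IQR) with quartiles at position `(n−1)·q` (R type
7), stated explicitly because software conventions differ. The paired
Wilcoxon signed-rank test discards zero differences (classic variant) and
mid-ranks ties; tie-free samples use the exact signed-rank null, tied
samples a seeded Monte-Carlo null (10⁵ sign assignments), and a
normal-approximation path with tie and continuity corrections is
available. All-zero differences return p = 1 with a degenerate flag. No
multiple-testing correction is applied by default, matching the common
reporting convention for such studies. "Median relative difference"
is reported as the difference of medians (the reading under which
published kidney figures of 0.5%/2.2% reproduce from their printed
medians); per-case differences are available from the raw tables.

## Numerical choices and test scales

* Alignment tolerance 1e-6 mm on spacing; kernel round-trips asserted to
  1e-12; oracle agreement to 1e-9 mm.
* Mask thresholding at 0.5 everywhere (file ingestion and warps).
* The synthetic S-value kernel puts an exact `self_fraction` of its mass
  in the centre voxel and distributes the remainder as `exp(−r/range)`
  truncated at `3·range`; its default total normalisation deposits the
  mean ¹⁷⁷Lu beta energy per decay (0.1475 MeV) in a water-density voxel,
  so a uniform 1 MBq/mL concentration yields ≈2.36e-5 Gy/s interior dose
  rate at any voxel size. With `self_fraction = 1` the kernel is purely
  local, which makes uniform-concentration phantoms analytically solvable
  (used by the recovery tests at 1e-6 relative tolerance).
* Test problem sizes: oracle comparisons run on ≥200 random lattices up
  to 12³ with random anisotropic spacing; cohort-level properties run on
  a full 23-case cohort at the default 48×64×64 grid; unit tests use a
  geometrically scaled-down phantom (24×32×32 at 6 mm). These sizes keep
  the full suite near a minute while exercising every code path at study
  scale.

## Known limitations

* No resampling: all volumes, masks and kernels must share one grid.
* Zero-padded convolution loses dose for sources within one kernel extent
  of the lattice edge.
* The displacement-field warp does not preserve topology and can, at
  extreme σ, empty a small mask (an error, by design).
* Gross-failure "bleeding" grows the mask geometrically toward the
  neighbour without respecting tissue boundaries.
* The exact Wilcoxon path requires tie-free absolute differences; with
  heavy ties the Monte-Carlo p-value carries simulation noise of order
  1/√n_mc.
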