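# voxdosim

Voxel-level dosimetry and contour-agreement evaluation for
¹⁷⁷Lu-DOTATATE SPECT/CT, driven by a seeded synthetic phantom-cohort
generator.

In ¹⁷⁷Lu-DOTATATE radionuclide therapy the absorbed dose to the organs at
risk (kidneys, liver, spleen) is estimated from quantitative SPECT/CT, and
the organ contours that define those doses are increasingly drawn by
automatic segmentation. Evaluating such a workflow needs three pieces of
machinery, all of which this package provides for R users working on
aligned 3-D voxel grids:

1. **Contour agreement metrics.** For two segmentations *A* and *B*:
   the Dice similarity coefficient
   `DSC(A,B) = 2|A ∩ B| / (|A| + |B|)`,
   the Hausdorff distance
   `HD(A,B) = max(h(A,B), h(B,A))` with
   `h(A,B) = max_{a∈∂A} min_{b∈∂B} ‖a − b‖`,
   and the mean distance to agreement (MDA), the same construction with
   the maximum replaced by a mean. Boundaries are 6-connectivity surface
   voxels; distances are in mm using the physical voxel spacing. Tolerance
   criteria (DSC ≥ 0.800, HD ≤ 3.0 mm, MDA ≤ 3.0 mm) and criteria-rate
   bookkeeping are built in.
2. **Single-time-point voxel dosimetry.** Count rates are converted to
   activity with a scanner cross-calibration factor (cps/MBq), CT is
   converted to mass density through a piecewise-linear HU table, the
   activity map is convolved with a voxel S-value kernel (MIRD voxel-level
   formalism) to a dose-rate map, and one time point is integrated with
   the Hänscheid estimator `D = Ḋ(t) · 2t / ln 2`, which needs no per-patient
   effective half-life. The closed-form bias of that estimator,
   `r = (t/T)·2^(1−t/T)` for an organ with effective half-life `T`, is
   exposed directly.
3. **Cohort machinery.** A seeded ellipsoid-organ phantom generator
   (liver with lesions and occasional hepatomegaly, spleen absent in a
   configurable fraction of cases, kidneys with a cold renal-pelvis
   exclusion, Gaussian system blur + Poisson counts, smooth observer
   contour perturbations and rare gross segmentation failures) plus paired
   nonparametric statistics: median (IQR) and the exact Wilcoxon
   signed-rank test.

No clinical data ship with or are required by the package; every analysis
runs on synthetic cohorts that emulate the *statistical structure* of a
real evaluation study.

## Worked example

```r
library(voxdosim)

# How biased is a single-time-point dose estimate taken at 24.49 h
# when organ effective half-lives are ~51 h (kidneys), 67 h (liver),
# 68 h (spleen)?
sapply(c(kidneys = 51, liver = 67, spleen = 68), function(T)
  100 * (1 - underestimation_ratio(timing_params(24.49, T))))
#> kidneys   liver  spleen
#>    31.2    43.3    43.9     # percent underestimation

# A 23-case synthetic cohort: 4 manual observers + 1 AI-like contour per
# organ, evaluated against the reference and dosed through the full chain.
cfg     <- phantom_config()
cohort  <- generate_cohort(cfg, n_cases = 23, seed = 42)
metrics <- evaluate_cohort(cohort)
kernel  <- make_test_kernel(cfg$spacing_mm, self_fraction = 0.9, range_mm = 5)
doses   <- dose_cohort(cohort, kernel, cfg$calibration)
report  <- build_report(metrics, doses)

subset(report$accuracy, metric == "dsc")
#>           organ metric              manual          ai      p_value  n
#> 1         liver    dsc 0.964 (0.961-0.967)     1 (1-1) 2.767420e-02 23
#> 4        spleen    dsc 0.924 (0.918-0.933) 1 (0.999-1) 3.158569e-03 17
#> 7  kidney_right    dsc 0.912 (0.902-0.919) 1 (0.999-1) 2.384186e-07 23
#> 10  kidney_left    dsc   0.913 (0.9-0.921) 1 (0.999-1) 2.384186e-07 23
```

Each row gives the cohort median (IQR) of the Dice coefficient for the
manual and AI-like contours against the reference, with the paired
signed-rank p-value; n = 17 for the spleen because 6 of the 23 simulated
cases have no spleen. The dose table reads the same way for
Dmean/Dmax/Dmin in Gy:

```r
subset(report$dose, stat == "d_mean")[, c("organ", "ai", "reference", "p_ai", "n")]
#>               organ               ai        reference      p_ai  n
#> median         liver 5.74 (4.42-6.21) 5.74 (4.42-6.21) 0.7819061 23
#> median3       spleen  1.7 (1.46-2.45) 1.76 (1.56-2.45) 0.4375000 17
#> median6 kidney_right 2.48 (2.09-3.19)  2.48 (2.08-3.2) 0.5703125 23
#> median9  kidney_left 2.49 (2.09-3.05) 2.49 (2.09-3.05) 0.5703125 23
```

`run_pipeline()` chains all of the above (simulate → evaluate → dose →
report) from a single config list or YAML file and writes CSV/JSON
artifacts with an MD5 manifest, so a whole study re-runs reproducibly from
one seed.

## Documentation

The methods vignette (`vignettes/phantom-dosimetry-methods.Rmd`) documents
the models, the generator's study conditions, numerical choices and known
limitations. All exported functions carry roxygen documentation.
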