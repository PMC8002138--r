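# retidens

FWHM micro-densitometry and morphometry of retinal arteries from OCT
cross-section intensity profiles.

## What it does, and for whom

In an OCT B-scan a retinal artery crossed by a sampling line shows up as two
wall lobes on the intensity profile, separated by the lumen. `retidens` is
for researchers quantifying retinal arteriolar remodeling (e.g. in diabetes
or hypertension studies) from such scans. It localizes each wall boundary at
half of the lobe's peak height above its local background — full-width
half-maximum (FWHM) micro-densitometry — with sub-pixel precision, converts
the crossings to calibrated diameters, and derives the standard arteriolar
morphometry:

* outer diameter `RAOD` (outer-wall to outer-wall) and lumen diameter
  `RALD` (inner-wall to inner-wall), in µm via the 200 µm scale-bar
  calibration `um_per_px = 200 / pixels_per_200um`;
* wall thickness `AWT = (RAOD − RALD) / 2`;
* wall-to-lumen ratio `WLR = (RAOD − RALD) / RALD`;
* wall cross-sectional area `WCSA = (π/4)(RAOD² − RALD²)`.

Around the measurement it ships the statistics such studies report:
two-way absolute-agreement ICC (single and average measures, F-based CIs),
Bland–Altman analysis with a difference-vs-mean trend line, within-subject
coefficient of variation, normality-gated group comparisons with Tukey
post-hoc tests, chi-square for categorical data, per-group Pearson
correlation grids, and univariate / covariate-adjusted regressions with
standardized coefficients. Synthetic vessel phantoms (piecewise-constant
cross-section with exact analytic Gaussian blur and known ground truth) and
synthetic correlated cohorts make every stage testable without clinical
data; `run_pipeline()` chains the whole analysis deterministically.

## Worked example

Measure a blurred, noisy phantom whose true diameters are 130.71 / 97.21 µm
(blur σ = 4 µm, contrast-to-noise ≈ 33, 1 µm/pixel), then summarize
duplicate-measurement reliability across 85 vessels:

```r
library(retidens)

spec <- vessel_phantom_spec(130.71, 97.21, psf_sigma_um = 4, noise_sd = 3)
phantom <- generate_vessel_profile(spec, seed = 7)
m <- measure_vessel(phantom$profile, calibrate_scale(200))
m
#> FWHM vessel measurement
#>   outer diameter (RAOD):   131.68 um
#>   lumen diameter (RALD):    96.47 um
#>   boundaries (px): 49.40, 66.83, 163.30, 181.08
#>   scale: 1.0000 um/px

set.seed(1)
truth <- data.frame(raod_um = rnorm(85, 130.71, 10.08),
                    rald_um = rnorm(85, 97.21, 8.10))
reps <- generate_repeat_measurements(truth, error_sd = 0.6, seed = 2)
mat <- as_repeats_matrix(reps, "raod_um")
icc_absolute_agreement(mat, "single")
#> ICC (two-way random, absolute agreement, single measures)
#>   ICC = 0.9947, 95% CI [0.9919, 0.9966] (n = 85 subjects, k = 2 sessions)
bland_altman(mat[, 1], mat[, 2])
#> Bland-Altman agreement (first - second)
#>   bias -0.0425, limits of agreement [-1.8869, 1.8018]
#>   trend: difference = 1.7934 -0.0139 * mean
coefficient_of_variation(mat[, 1], mat[, 2])
#> Within-subject CV (rms): 0.4986%, 95% CI [0.4336, 0.5867] (n = 85)
```

The single measurement lands within 1 µm of the true outer diameter and
0.8 µm of the true lumen despite blur and noise — the half-maximum point of
a blurred edge sits at the edge. With a 0.6 µm session error over vessels
whose true diameters spread ±10 µm, repeats agree almost perfectly
(ICC ≈ 0.995, CV ≈ 0.5%), the regime expected of a single trained grader.

Cohort-level analysis runs on data frames (synthetic or your own CSV via
`read_cohort_csv()`): `compare_groups()`, `pearson_grid()`,
`univariate_regression()`, `adjusted_regression()`. See the vignette
(`vignettes/fwhm-densitometry.Rmd`) for the model, parameter defaults and
design choices.

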