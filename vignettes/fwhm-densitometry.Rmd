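---
title: "FWHM micro-densitometry of retinal arteries: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FWHM micro-densitometry of retinal arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

A retinal artery crossed by a sampling line in an OCT B-scan produces a 1-D
intensity profile with two wall lobes — the anterior and posterior vessel
walls — separated by the lumen. Micro-densitometry estimates the vessel
geometry from this profile alone: each wall boundary is placed where the
intensity crosses half of the lobe's peak height above its local background
(full-width half-maximum, FWHM). The distance between the two *outer*
crossings is the retinal artery outer diameter (RAOD); between the two
*inner* crossings, the lumen diameter (RALD). A scale calibration taken from
the 200 µm scale bar of the scan converts pixels to micrometres
(`um_per_px = 200 / pixels_per_200um`).

From the two diameters the standard arteriolar morphometry follows:

* wall thickness `AWT = (RAOD − RALD) / 2`,
* wall-to-lumen ratio `WLR = (RAOD − RALD) / RALD = 2·AWT / RALD`,
* wall cross-sectional area `WCSA = (π/4)(RAOD² − RALD²) = π·AWT·(RALD + AWT)`.

The two algebraic identities on the right are exact and are enforced by
property tests at 1e-9 relative error.

The rationale for half-maximum localization is the behaviour of a blurred
step edge: convolving a step with any symmetric point-spread function leaves
the 50%-contrast point exactly at the step position. FWHM therefore
localizes edges with sub-pixel accuracy and is first-order insensitive to
the blur scale — within limits discussed below.

## Measurement pipeline and its parameters

`measure_vessel(profile, calib, config)` runs three stages.

**Lobe detection** (`detect_wall_lobes`). The profile is optionally smoothed
by a centered moving average (`smoothing_window_px`, odd, default 1 = off;
crossings are computed on the smoothed signal so that detection and
localization see the same data). After polarity normalization the two wall
lobes are the pair of local maxima with the greatest summed topographic
prominence whose peaks are at least `min_lumen_px` apart (default 10 px);
among equally prominent pairs the one whose midpoint is closest to the
profile centre wins, since the grader centres the sampling line on the
vessel. Fewer than two qualifying lobes is a "no vessel found" error; a flat
profile is "no contrast".

**Polarity** (`polarity = "auto"`, the default). Whether walls appear bright
or dark depends on the display inversion of the exported scan, so both
dialects must be supported. Auto mode runs the detector on the signal and on
its negation and keeps the orientation whose best lobe pair is more
prominent. This criterion is antisymmetric under intensity inversion —
inverting the image yields the identical boundaries — and, unlike comparing
the centre median against the end median, it keys on the walls themselves
rather than on the lumen-versus-background brightness, which is
uninformative when the lumen is darker than the surrounding tissue (the
common appearance of arterial blood in OCT).

**Half-maximum localization** (`half_max_crossings`). Each lobe's baseline
is the median of the `baseline_fraction` (default 0.10) of samples on that
lobe's *outer* side — a local background, robust to asymmetric illumination;
the half level is midway between baseline and peak. Walking outward and
inward from the peak, the first sample interval straddling the half level is
found and the crossing located by linear interpolation between the two
straddling samples. No parabolic refinement is applied: linear interpolation
matches the first-crossing semantics and keeps the estimator monotone in the
data. Because the half level is defined *relative to the baseline*, boundary
positions are exactly invariant under affine intensity maps `I → aI + b`
(`a > 0`), verified to 1e-9 px.

## The vessel phantom generator

`vessel_phantom_spec()` + `generate_vessel_profile()` render the study
conditions the measurement is validated against: a piecewise-constant
cross-section — background | wall annulus | lumen | wall annulus |
background — convolved with a Gaussian PSF and sampled with additive i.i.d.
Gaussian noise. Because the ideal profile is a sum of boxcars, the
convolution is evaluated in closed form through the normal CDF: the sampled
phantom carries its blur *exactly*, and the pre-blur edge positions (the
ground truth) are known to machine precision. A sample landing exactly on an
edge takes the midway intensity, the σ → 0 limit of the analytic blur.

Defaults, chosen once as realistic for magnified exported B-scans:

* sampling 1 µm/pixel; window extending 50 µm beyond each outer edge
  (must cover ≥ 3σ of blur, enforced);
* wall intensity 160, lumen 60, background 60 (arbitrary units): bright
  walls, lumen at the local background level;
* blur σ = 4 µm and noise SD 3 for the end-to-end pipeline, i.e. a
  wall-to-background contrast-to-noise ratio ≈ 33.

The equal lumen/background level is deliberate: half-maximum localization of
a transition is unbiased only when both sides of the edge share the
reference level from which the half is taken. If the lumen is darker or
brighter than the perivascular tissue, the inner crossings shift by roughly
`σ·Δ/slope` (Δ the level mismatch) — a bias of the FWHM method itself that
the phantom makes visible when configured that way, not a rendering
artefact. Speckle-like multiplicative noise is out of scope; noise is
i.i.d. Gaussian.

**Blur bias.** For blur σ well below the wall thickness, the measured
diameters stay within one sampling step of truth (the blurred-step
argument). This degrades gracefully but genuinely: once σ approaches half
the wall thickness, the two edges of a wall interact, the lobe peak erodes
below the true plateau (peak = `2Φ(w/σ) − 1` of the plateau for wall
half-width `w`), the half level drops with it, and the crossings move
outward by several µm. The property suite therefore asserts the one-step
bound for σ up to AWT/4, where it provably holds; at σ = AWT/2 the bias is
≈ 3 µm and the bound is not claimed. The Monte-Carlo recovery check (σ =
4 µm, noise at CNR 33, 100 seeds) shows mean absolute error ≈ 0.4 µm for
both diameters against the 1 µm acceptance bound.

## Repeats, eyes, and the reliability battery

Every vessel is measured in two sessions; the two readings are averaged
per vessel, per-vessel AWT/WLR/WCSA are computed from the averaged
diameters, and the four largest arteries per eye (largest by averaged RAOD,
ties by input order) are averaged into a single value set per eye. Averaging
per-vessel derived values, rather than recomputing them from per-eye mean
diameters, follows the measured → averaged → calculated ordering; the
alternative is available via `aggregate_eye(derived =
"from-mean-diameters")`. The two conventions coincide for AWT (linear) and
differ in general for WLR and WCSA — a regression test documents a
counterexample rather than asserting a false identity.

Reliability of the duplicate measurements is summarized by:

* **ICC, two-way random effects, absolute agreement** (McGraw–Wong
  ICC(A,1) and ICC(A,k)) computed from the two-way ANOVA mean squares, with
  the standard F-based confidence interval (average-measure bounds by
  Spearman–Brown transformation of the single-measure bounds). The
  implementation is tested against a definitional sums-of-squares oracle on
  random matrices at 1e-9. ICC(A,1) ≤ ICC(A,k) holds whenever the subject
  mean square exceeds the error mean square (nonnegative ICC); the order
  reverses algebraically for negative ICCs, so the property is asserted on
  the nonnegative regime. A zero-variance matrix yields an explicit
  degenerate result rather than a number.
* **Bland–Altman**: differences are first − second; bias ± 1.96·SD limits
  of agreement; ordinary least squares of difference on pairwise mean gives
  the plotted trend line.
* **Within-subject coefficient of variation**, root-mean-square form
  `CV = 100·sqrt(mean((dᵢ²/2)/mᵢ²))`; the per-subject SD/mean variant is
  available behind `method = "sd-mean"`. The confidence interval applies
  chi-square bounds with n degrees of freedom to the within-subject
  variance — one documented choice among several in use, since CV interval
  constructions are not standardized.

## The synthetic cohort and its statistics

`default_cohort_spec()` emulates a three-group study — 32 healthy control
eyes, 32 diabetic eyes without retinopathy (NDR), 21 with mild
non-proliferative retinopathy (NPDR) — with group-wise means and SDs for
demographics, arterial morphometry, and ETDRS-sector thicknesses of the
ganglion cell layer (GCL), macular RNFL, peripapillary RNFL and total
retina. Continuous variables are a linear transform of correlated
standard-normal latents (symmetric square root of the target correlation
matrix), so sample moments and the targeted Pearson correlations converge to
the spec values as n grows; binary covariates are independent Bernoulli
draws. A correlation set that does not assemble into a positive
semi-definite matrix is rejected up front with the targeted pairs named.

Only the correlations the analysis exercises are imposed: GCL–macular-RNFL
sector pairs (central 0.81/0.68/0.78 across groups, inner-inferior
0.61/0.68/0.46, outer-superior 0.35/0.54/0.48), WCSA–central GCL 0.353, and
RAOD–RALD 0.85 for physical plausibility. Everything else is left at zero —
in particular the generated morphometry columns are marginal draws, not
values linked by the wall equations, which is sufficient for exercising the
statistics but means the cohort table should not be used to test the
morphometry identities. Diabetes-specific covariates are `NA` in controls,
and all statistics run on complete cases.

The statistical battery mirrors common ophthalmic-cohort practice:
Kolmogorov–Smirnov normality (against a normal with the sample mean and SD,
gated per variable pooled across groups, α = 0.05), one-way ANOVA with
Tukey-adjusted pairwise post-hoc p-values or Student's t-test for normal
variables, Kruskal–Wallis otherwise; Pearson chi-square without continuity
correction for categorical data (expected counts ≥ 1 required); per-group
Pearson correlation grids; and univariate plus covariate-adjusted OLS
regressions. Regressions report the *standardized* coefficient
`slope·SD(x)/SD(y)` — which in the univariate case equals the Pearson
correlation exactly, a 1e-9 cross-check against the correlation grid —
alongside the unstandardized slope and its confidence interval, because the
two are easily conflated in published tables. Default adjustment covariates
are age, gender (male = 1, female = 0), diabetes duration and HbA1c;
rank-deficient designs are rejected with the collinear columns named.

## The pipeline and problem sizes

`run_pipeline(run_config(...))` chains simulate → measure → morphometry →
reliability → cohort, writing each stage's artifacts (CSV/JSON) and a
manifest of MD5 hashes; identical configuration and seed give identical
manifests, and a stage whose upstream artifact is absent aborts naming it.
The default run simulates 6 eyes × 4 arteries × 2 sessions of blurred,
noisy phantoms plus an 85-eye cohort — sizes chosen so a full run completes
in seconds while every stage still operates on non-trivial data. The test
suite uses the same scale, with larger draws (n = 2000–10000) only where a
convergence claim is being checked.

## What passing tests do and do not show

The phantoms establish correctness of the estimator under its own model:
symmetric Gaussian blur, additive Gaussian noise, a straight sampling line
through the vessel centre, lumen at background level. Real B-scans add
speckle, curved and obliquely-cut vessels, neighbouring structures
(vein walls, reflective bands) that can out-compete a wall lobe, display
gamma, and lumen/background mismatch — none of which the suite exercises.
Likewise the cohort generator reproduces means, SDs and targeted
correlations, not the full joint distribution of a clinical sample, so the
statistics are validated for calibration and recovery, not for any clinical
conclusion. Automatic vessel localization in the B-scan and artery/vein
classification are out of scope: the sampling line and vessel identity are
inputs.
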