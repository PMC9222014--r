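---
title: "Quantifying bone-marrow edema in spine STIR MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone-marrow edema in spine STIR MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmetex)
```

## The problem

Bone-marrow edema (BME) is inflammatory fluid in vertebral marrow and the key
MRI sign of active axial involvement in spondyloarthritis, including axial
psoriatic arthritis. On short-tau-inversion-recovery (STIR) images, edema is
hyperintense against the dark fat-suppressed marrow, and clinical questions —
for example whether vigorous exercise changes the edema burden between two
scans — are answered by three complementary readings of the same images:

1. a codified radiological positivity rule (hyperintensity in two or more
   sites and/or two or more slices),
2. semi-quantitative SPARCC spine scoring (six most abnormal disco-vertebral
   units, three sagittal slices each, maximum 108), and
3. quantitative per-voxel texture features compared between edema and healthy
   marrow, and longitudinally between groups.

`bmetex` implements all three readings as a reproducible pipeline, together
with the intensity preprocessing they require and a synthetic spine phantom
that stands in for patient data (which, for such cohorts, are typically not
shareable). Everything downstream of segmentation is covered; manual
segmentation itself, DICOM ingestion, and pulse-sequence simulation are out
of scope. Masks, annotations, and metadata are inputs.

## The phantom

`phantom_spec()` describes a sagittal STIR-like spine: stacked vertebral
bodies of dark marrow (default mean 100, arbitrary units), bright CSF in the
spinal canal (200), STIR-bright intervertebral discs (140), mid-grey
paraspinal soft tissue (70), and hyperintense lesions (+60 over marrow)
seeded at vertebral corners, where inflammatory corner lesions concentrate in
axial disease. The intensity *ordering* (CSF > lesion > disc > marrow > soft
tissue) is what matters; the numbers are configurable defaults, not claims
about scanner units. Discs and soft tissue are modelled explicitly because
3x3 windows centred on corner lesions straddle the vertebral boundary: an
air-like surround would leak non-anatomical near-zero values into
window-minimum and gradient features.

Each scan is degraded by a smooth multiplicative bias field (random
second-order polynomial, mean exactly 1, peak deviation `bias_amplitude`,
default 0.2) and Rician noise (`sqrt((x + n1)^2 + n2^2)` with Gaussian
channels of SD `rician_sigma`, default 5) — the standard magnitude-MRI noise
model. Ground truth (lesion/marrow/CSF masks, the true bias field, per-lesion
unit, quadrant, depth and intensity records, and the noise-free volume) is
returned alongside, so every downstream stage can be checked against
construction.

A cohort is two arms (HIIT and control, 19 patients per arm by default,
matching a realistic exercise-trial size) at two timepoints.
`time_group_effect` adds extra lesion contrast at week 11 in the HIIT arm
only — the known interaction the longitudinal model must recover; its default
is 0 (the null case). Every scan's random stream derives from
`(seed, patient_id, timepoint)`, so any single scan can be regenerated in
isolation and cohorts are bit-reproducible.

What the phantom does *not* emulate: partial-volume effects, anatomical
variation of vertebral shape, T1-weighted contrast, motion or ghosting, and
spatially correlated noise. Tests passing on the phantom therefore
demonstrate correctness of the computational pipeline under controlled
conditions, not clinical performance on patient images.

## Preprocessing

Stages run in a fixed order: bias-field correction, histogram matching,
diffusion smoothing.

**Bias correction** (`correct_bias()`). The contract is behavioural: estimate
a smooth, strictly positive multiplicative field, normalized to mean 1 over
the region of interest, and divide it out; re-correcting a corrected scan
must change voxels by well under 1% RMS. The implementation fits a
second-order 3D polynomial to log-intensity over the spinal-column ROI by
Huber robust regression (robustness matters because hyperintense lesion
voxels sit inside the ROI and would otherwise tilt the fit). The fit is
evaluated on the full grid and exponentiated. On phantoms with amplitude-0.2
fields the estimated and injected fields correlate above 0.9 over marrow —
the recovery criterion the test suite enforces across 20 seeded scans.

**Histogram matching** (`match_histogram()`). A monotone piecewise-linear map
is built between 256 quantile landmarks of the input ROI and the atlas ROI,
then applied to the whole volume; beyond the observed ROI range the map
continues with slope 1, which makes matching a volume to itself the identity
everywhere (a property the tests assert). The atlas is a pinned scan id, by
default a seeded random pick from the cohort, recorded in the run manifest —
"randomly selected" is only reproducible if the selection is seeded and
logged. A constant-intensity ROI has no invertible CDF and is rejected.

**Perona-Malik diffusion** (`diffuse_pm()`). Edge-preserving smoothing with
the exponential conductance `g(x) = exp(-(x/K)^2)`, applied independently per
sagittal slice (the texture analysis is 2D, so smoothing is kept 2D as
well), with replicated borders. Two numerical choices deserve comment:

* *Update coefficient.* The scheme is parameterized by an integration
  constant (default 1/7) and a time step (default 0.01) whose product is the
  effective per-iteration coefficient (1/700 — very mild smoothing). The two
  factors are exposed separately because the composition conventions differ
  between implementations; every property the package tests holds for any
  stable coefficient, and values above the 4-neighbour stability bound of
  1/4 are rejected.
* *Conductance scale.* A raw conductance of 1.0 is meaningless on arbitrary
  intensity units, so `K` multiplies a robust per-slice gradient scale: the
  median nonzero absolute 4-neighbour difference, recomputed each iteration.
  This makes `conductance = 1` scale-free (doubling image intensities leaves
  the relative smoothing unchanged).

The update is applied in symmetric flux form, so the per-slice intensity sum
is conserved to floating-point accuracy; the suite checks conservation to
1e-6 relative and equality with an independently coded dense per-pixel
oracle to 1e-10 on 8x8 slices, plus monotone decrease of total variation.

## Texture features

Features are computed per voxel from an orthogonal 3x3 window centred on the
voxel, slice-wise, over segmented bone marrow. Centres must have a full
in-slice window (border voxels are excluded and counted); window pixels are
taken from the image regardless of mask membership, because 3x3 support at
thin mask edges would otherwise be undefined.

* **Intensity (i1-i7):** centre value, mean, median, sample SD (n−1),
  minimum, maximum, and semi-interquartile range `(Q3 − Q1)/2` with linear
  interpolation between order statistics (for 9 values the quartiles fall on
  order statistics 3 and 7 exactly).
* **Gradient (g1-g10):** from Sobel `Gx`/`Gy` maps (replicate borders; unit
  ramp along x gives an interior response of exactly 8) and the magnitude
  `|G|`: the set comprises the window sums of `|Gx|+|Gy|` and `|G|`, the
  mean, median, SD, semi-IQR, centre, min and max of `|G|`, and the mean
  anisotropy `||Gx|−|Gy||`. This ten-feature set is the package's canonical
  definition: it preserves the count, the Sobel operator, and the windowing
  convention, and is labelled as such in outputs (published gradient-feature
  sets vary and are often not fully specified).
* **GLCM (f1-f4):** grey levels from per-scan global min-max quantization to
  8 levels (configurable); one non-symmetric co-occurrence matrix per
  orientation (0, 45, 90, 135 degrees) at distance 1; contrast, correlation,
  energy and homogeneity per orientation, averaged over orientations. The
  f1..f4 assignment follows the alphabetical order of the four standard
  co-occurrence properties. Correlation is undefined on zero marginal
  variance; undefined orientations are excluded from the mean rather than
  imputed as 0 or 1 (imputation would bias cohort summaries), and `f2` is
  reported missing only when all four orientations are undefined — the one
  feature allowed to be missing.

The production extractor is vectorized over all windows of a slice; the
exported per-window functions (`intensity_features()`, `gradient_features()`,
`glcm_features()`) are the readable reference semantics, and the suite checks
the two paths against each other and against a brute-force pair-enumeration
oracle to 1e-12.

For edema-versus-healthy comparisons, healthy reference voxels are drawn as
a seeded uniform sample, matched in count to the lesion voxels, from marrow
excluding lesions dilated by one voxel (26-connectivity) — adjacency
exclusion keeps partial-lesion windows out of the healthy pool.

## SPARCC scoring

The scorer codifies the standard spine scheme: per disco-vertebral unit,
three consecutive sagittal slices are scored; each of four quadrants with at
least one lesion voxel on a slice scores 1; per slice, one bonus point for a
deep lesion and one for an intense lesion; at most 18 per unit; the six
highest-scoring units sum to the total (0-108). Decisions the published
summary score sheet leaves open are fixed as follows, deterministically:

* the slice triple per unit is the one maximizing the unit score, ties going
  to the lowest slice index; unit ties go to the most cranial unit;
* *depth*: a vertebra contributes only when the lesion reaches the unit's
  disc-adjacent half (a lesion at the far end of a vertebra belongs to the
  neighbouring unit); the extent is then measured in mm from that endplate
  over the full vertebral body, and >= 10 mm scores the bonus;
* *intensity*: slice lesion mean at least `intense_fraction` (default 0.75)
  of the median CSF reference intensity — "CSF-like brightness" is nowhere
  quantified, so the fraction is exposed as a parameter;
* bonuses are awarded per slice, consistent with the 108 maximum
  (6 x (4x3 + 3 + 3)).

Changes between baseline and follow-up are categorized at the minimally
important change of 5 points (`categorize_change()`), and the radiological
positivity rule (`bme_positive()`) is true when lesions occupy two or more
units and/or two or more slices.

## Statistics

* **Voxel model** (`lmm_status()`): feature ~ status with random intercepts
  for patient and scan (scan is nested within patient; unique scan ids make
  the two crossed terms equivalent to nesting), REML, Wald z p-value on the
  status coefficient. Degenerate (e.g. noise-free) data give singular fits:
  these are flagged, fall back to ordinary least squares when the mixed fit
  collapses entirely, and still report a p-value with a warning.
* **Change model** (`lmm_change()`): per-scan lesion feature means (lesions
  cannot be matched across timepoints, so scan means are the response),
  fixed effects time (reference = baseline), intervention (sum-coded: HIIT
  +1, control −1) and their interaction, random intercept per patient, Wald
  z on the interaction. Under sum coding the interaction equals half the
  HIIT-minus-control difference in change, and swapping group labels flips
  its sign.
* **Bonferroni**: q = min(1, m p) with m = 21, the feature-family size,
  applied separately per model family; m is recorded in every report.
* **Wilcoxon signed-rank** (`wilcoxon_paired()`): zero differences dropped
  (classical convention, count reported); exact two-sided p by
  generating-function enumeration over all sign assignments for up to 25
  pairs (doubled midranks keep tied ranks integral), normal approximation
  with tie and continuity correction above.
* **Fisher's exact probability test** (`fisher_exact()`): Freeman-Halton
  extension on 2x2 and 2x3 tables by exhaustive enumeration of all tables
  with the observed margins, summing probabilities not exceeding the
  observed table's (relative slack 1e-7 plus 1e-12 for floating-point
  ties). Change reports test the 2x3 group-by-category table and also
  report the 2x2 collapse (any change vs none), since printed exact-test
  p-values in the literature cannot always be attributed to one layout.

## Verification strategy and problem sizes

Every numerical component is tested against an independent oracle: GLCM
against exhaustive pair enumeration, diffusion against a dense per-pixel
reimplementation, the exact tests against full enumeration and against the
base-R implementations where they overlap, bias correction against the
injected ground-truth field, and SPARCC against hand-counted constructions
(a fully positive synthetic spine reaches exactly 108). Statistical
properties are checked by simulation: the voxel model's type-I error at
nominal 5% over 1000 null simulations (16 patients x 2 scans x 30 voxels
per status each), interaction power over 50 seeded phantom cohorts at the
large-effect setting (`time_group_effect = 30` against `rician_sigma = 5`,
6 patients per arm), and the null longitudinal pipeline over 20 seeded
end-to-end cohorts at the study-sized 19 patients per arm, where no feature
should survive Bonferroni in at least 95% of replicates. Phantom grids in
the suite are 48x40x6 voxels with four vertebrae — large enough to hold
three scoreable units and corner lesions, small enough to keep the whole
suite to a few minutes.

## Known limitations

* The gradient-feature set and several SPARCC operational details are
  package-canonical reconstructions of under-specified published
  procedures; absolute feature magnitudes are not comparable to other
  implementations, and all intensity features are scale-dependent by
  design (preprocessing, not the features, provides comparability).
* Bias correction assumes a low-order smooth field; pathological
  high-frequency inhomogeneity is out of model.
* Wald z p-values are mildly anticonservative for small cohorts; with
  study-sized cohorts (about 20 per arm) the family-wise error after
  Bonferroni is controlled in simulation, but very small cohorts with few,
  tiny lesions can produce unstable scan means and spurious interaction
  signals.
* The phantom's geometric regularity (identical vertebrae, axis-aligned
  quadrants) means annotation-handling code is exercised only on simple
  geometry; real 3D Slicer annotations with oblique spines would need the
  same JSON schema but have not been tested here.
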