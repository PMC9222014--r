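# bmetex

Quantitative analysis of bone-marrow edema (BME) in sagittal STIR MR images
of the spine, for imaging scientists and rheumatology researchers studying
axial spondyloarthritis / psoriatic arthritis. The package implements the
three standard readings of such images as one tested, reproducible pipeline:

* **Preprocessing** — multiplicative bias-field correction, ROI-restricted
  histogram matching to an atlas scan, and Perona–Malik anisotropic
  diffusion `I ← I + c · Σₙ g(|∇ₙI|) ∇ₙI`, `g(x) = exp(−(x/K)²)`, applied
  per sagittal slice in conservative flux form.
* **Texture feature maps** — 21 per-voxel features from an orthogonal 3×3
  sliding window over segmented marrow: seven intensity features (i1–i7),
  ten Sobel-gradient features (g1–g10), and four grey-level co-occurrence
  features (f1–f4: contrast, correlation, energy, homogeneity, averaged
  over the 0°/45°/90°/135° orientations at distance 1).
* **SPARCC spine scoring** — computerized scoring of lesion masks: six most
  abnormal disco-vertebral units × 3 consecutive slices × 4 quadrants, plus
  per-slice depth (≥ 10 mm) and intensity (CSF-referenced) bonuses, maximum
  108; change categorization at the minimally important change of 5; the
  two-sites/two-slices positivity rule.
* **Statistics** — voxel-level linear mixed model (status fixed effect;
  patient and scan random intercepts), longitudinal mixed model on per-scan
  lesion means (time, sum-coded intervention, and their interaction),
  Bonferroni correction (q = min(1, m·p), m = 21), exact Wilcoxon
  signed-rank, and the Freeman–Halton Fisher exact test by exhaustive
  enumeration.
* **Synthetic spine phantom** — STIR-like cohorts (dark marrow, bright CSF,
  corner lesions, bias field, Rician noise, two arms × two timepoints, a
  configurable time×group lesion effect) with full ground truth, so every
  stage is testable without patient data.

## Worked example

Generate one phantom scan, score it, and extract the voxel feature table:

```r
library(bmetex)

spec <- phantom_spec(image_shape = c(48L, 40L, 6L), n_vertebrae = 4L,
                     lesion_radius_mm_range = c(2, 4),
                     lesion_count_range = c(1L, 3L), seed = 42L)
scan <- generate_scan(spec, "P001", "baseline", "control")
scan$volume
#> <bme_volume 'P001_baseline'> 48x40x6 voxels, spacing 1.2x1.2x3.3 mm, slice axis 3
scan$truth$lesions
#> # A tibble: 3 × 5
#>   level quadrant depth_mm intense n_voxels
#>   <chr> <chr>       <dbl> <lgl>      <int>
#> 1 V1-V2 ip            4.8 TRUE          10
#> 2 V2-V3 ip            4.8 TRUE          12
#> 3 V3-V4 ia            4.8 TRUE          10
```

Three corner lesions were planted, each recorded with its disco-vertebral
unit, quadrant, depth from the endplate in mm, and brightness flag. The
SPARCC scorer reads the lesion mask and the image:

```r
sparcc_total(scan$truth$labelmap, scan$volume, scan$truth$annotation)
#> <bme_sparcc> total 8 / 108 over 3 units
#>   unit   rank slice_start quadrant_points depth_points intensity_points score
#> 1 V1-V2     1           2               1            0                1     2
#> 2 V2-V3     2           2               1            0                2     3
#> 3 V3-V4     3           2               1            0                2     3
```

Each lesion hits one quadrant; none reaches 10 mm depth, so no depth
points; the bright ones earn per-slice intensity points. A score change of
39 → 50 between timepoints would be categorized as
`categorize_change(39, 50)` → `"increased"` (change ≥ 5).

Feature extraction pairs every lesion voxel with a matched healthy marrow
voxel and summarises by status:

```r
ft <- extract_matched_features(scan$volume, scan$truth$labelmap,
                               meta = list(patient_id = "P001",
                                           group = "control",
                                           timepoint = "baseline"),
                               seed = 1)
dplyr::count(ft, status)
#>   status      n
#> 1 BME        32
#> 2 healthy    32
summarize_features(ft, "status")
#>   feature status      n  mean    sd degenerate
#> 1 i1      BME        32  162.  8.01 FALSE
#> 2 i1      healthy    32  101.  8.46 FALSE
#> 3 i2      BME        32  140. 14.0  FALSE
#> ...
```

Lesion voxels are brighter (i1 ≈ 162 vs 101: the phantom's marrow mean 100
plus lesion contrast +60, under noise), the direction reported for BME in
the clinical literature. `run_all(config, out_dir)` chains
simulate → preprocess → features → SPARCC → statistics over a whole cohort
and writes `table4.csv` (BME vs healthy with voxel-model p/q values),
`table5.csv` (per-arm lesion summaries with interaction p/q),
`change_tables.json` (Fisher tests on change categories) and a checksummed
manifest; `inst/cli/bmetex.R` exposes the same stages as shell
subcommands.

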