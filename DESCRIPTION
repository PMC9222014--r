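Package: bmetex
Title: Texture Analysis and SPARCC Scoring of Bone Marrow Edema in Spine MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantitative analysis of bone marrow edema (BME) in
    sagittal STIR magnetic resonance images of the spine: intensity
    preprocessing (multiplicative bias-field correction, ROI-restricted
    histogram matching, Perona-Malik anisotropic diffusion), pixel-wise
    texture-feature maps (intensity, Sobel-gradient and grey-level
    co-occurrence matrix features over a sliding 3x3 window), computerized
    SPARCC spine scoring of lesion masks with change categorization, and the
    accompanying statistical layer (voxel-level and longitudinal linear mixed
    models, exact Wilcoxon signed-rank and Freeman-Halton Fisher tests,
    Bonferroni correction). Includes a synthetic STIR-like spine phantom
    generator with ground truth, so that every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
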