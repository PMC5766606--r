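Package: prfmap
Title: Population Receptive Field Mapping with Synthetic Retinotopy and
    Map-Coherence Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and estimation of population receptive
    fields (pRFs) from visual-field mapping fMRI experiments that use
    bar-sweep stimuli confined to a central "carpet" region, including
    illusory-contour (Kanizsa), occlusion and low-contrast luminance
    bars.  Provides the display-geometry and run-design encoding of the
    experiment, rasterized binary stimulus apertures, a 2-D isotropic
    Gaussian pRF model with double-gamma haemodynamic convolution,
    coarse-to-fine parameter estimation with goodness of fit, a
    ground-truth synthetic fMRI generator with per-area signal-to-noise
    gradients, and the map-coherence statistics used to compare
    retinotopic maps across stimulus conditions: quadrant ROI filtering,
    responsive-vertex proportions, Fisher-z averaged prediction
    correlations with a vertex-shuffle permutation test, Spearman and
    circular parameter correlations, and gaze-stability summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
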