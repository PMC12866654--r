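Package: ichagree
Title: Synthetic Phantoms and Agreement Statistics for Intracerebral
    Haemorrhage Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic three-dimensional haematoma phantoms on
    CT-like voxel grids and measures their volumes by voxel counting, by
    the bedside ABC/2 estimator with Kothari slice weighting, and by a
    parametric simulator of fully automated segmentation with realistic
    failure modes (missed small haematomas, inclusion of intraventricular
    blood and other hyperdensities, partial segmentation). Provides the
    statistical machinery of method-comparison studies for haemorrhage
    volumetry: Bland-Altman limits of agreement with heteroscedasticity
    screening by Kendall's tau and log back-transformed mean-dependent
    limits, one-way intraclass correlation for inter-observer
    variability, paired t and Shapiro-Wilk tests, subgroup analyses, a
    clinical acceptability rule, and sample-size/power calculations for
    limits-of-agreement studies, together with an end-to-end study
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
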