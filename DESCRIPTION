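Package: cardiomap
Title: Agreement of Electroanatomical Voltage Maps and MRI Late-Enhancement
    Transmurality Maps on a Left-Ventricle Infarct Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing catheter-based electroanatomical (unipolar and
    bipolar voltage) maps of the left ventricle against cardiac-MRI
    late-enhancement transmurality maps. Provides a synthetic left-ventricle
    infarct phantom with a ground-truth transmurality field, an MRI-like
    renderer with 2SD scar segmentation and midline radial-projection
    transmurality polar maps, a sparse-point voltage polar-map builder with
    threshold classification and iterative bipolar-threshold calibration,
    RGB colour-scale round-tripping of rendered maps, and agreement
    statistics: overlap (Dice-equivalent) ratios, Pearson correlation with
    qualitative grading, least-absolute-residual robust regression,
    Bland-Altman analysis, and ROC-based cut-off derivation. A cohort runner
    orchestrates phantom generation, both pipelines and the comparison into
    a reproducible experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
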