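Package: atypkd
Title: Atypical ADPKD Imaging Volumetrics and Cohort Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing atypical (Mayo Class 2) autosomal dominant
    polycystic kidney disease from T2-weighted abdominal MRI. Implements automated
    total-cyst-volume segmentation by progressive-weighted-curve (PWC) histogram
    threshold selection with feature-scored candidate thresholds, kidney volumetrics
    (TKV, htTKV, TCV, RTV and their ratios), the Mayo imaging classification,
    eGFR-slope progression analysis, and cohort statistics. Ships a 12-patient
    atypical-ADPKD reference cohort and a 3-D kidney phantom generator with known
    ground-truth volumes for validating the segmentation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
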