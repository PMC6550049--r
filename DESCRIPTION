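Package: edmorph
Title: Euclidean Distance Matrix Analysis of 3D Anatomical Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based morphometric comparison of two groups of
    specimens by Euclidean distance matrix analysis (EDMA): form matrices
    of all unique inter-landmark distances, sample mean-form estimation,
    form-difference matrices of like-distance ratios, non-parametric
    bootstrap confidence intervals and a bootstrap test of mean-form
    equality, effect-band classification of significant distances, and
    principal component analysis of ln-transformed inter-landmark
    distances. Includes replicate-digitization averaging with quality
    control, regional landmark subsets, bilateral (left/right) matching
    for asymmetry analysis, and a synthetic landmark-data generator for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
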