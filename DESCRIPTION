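Package: wmlseg
Title: Tri-Planar Dense U-Net Segmentation and Anatomical Classification
    of White-Matter Lesions on FLAIR MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end segmentation of multiple-sclerosis white-matter
    lesions from 3D FLAIR volumes using three orientation-specific 2D
    densely connected U-Nets fused by per-voxel majority voting. Includes
    histogram-landmark intensity standardization, Tversky-loss training
    with early stopping and a cross-validation harness, CSF-based
    false-positive removal, anatomical lesion classification
    (periventricular, juxtacortical, infratentorial, deep white matter)
    with confluent-lesion counting via intensity local maxima, a full
    voxel- and object-level evaluation suite (Dice, object Dice, PPV,
    object-level detection rates, average symmetric surface distance),
    and a synthetic brain phantom generator so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
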