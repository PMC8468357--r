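Package: radrepro
Title: Reproducibility of Radiomic Features Under Manual and
    Semi-Automatic Tumour Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing the
    reproducibility of radiomic features extracted from 3D medical image
    volumes under different tumour segmentation strategies.  Provides a
    synthetic phantom study generator emulating manual delineation by
    multiple observers and semi-automatic flood-fill segmentation, a
    662-feature radiomic extractor (first-order, shape, grey-level
    co-occurrence, run-length and dependence matrix features, with
    undecimated wavelet channels), and ANOVA-based intraclass correlation
    analysis with reproducibility banding and non-parametric
    between-method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
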