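Package: Ki67Global
Title: Global Ki-67 Immunohistochemistry Quantification for Whole Tumour Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Whole-section (global) quantification of Ki-67 immunohistochemistry
    in H-DAB stained brightfield images. Provides colour deconvolution into
    hematoxylin and DAB optical densities, classical nucleus segmentation with
    four-band intensity classification (negative, weak, moderate, strong),
    region-of-interest masking from polygon annotations, per-slide proliferation
    metrics (proliferation index, H-score, positive and strong nuclear
    densities), maximal fixed-area hotspot search with the Webster
    dichotomisation, slide quality scoring, and a cohort statistics layer
    (rank tests, Spearman correlation, median-dichotomised Kaplan-Meier and
    univariable Cox regression). A synthetic slide generator with planted
    ground truth makes every stage testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    survival,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
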