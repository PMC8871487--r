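Package: radstab
Title: Segmentation-Stability Analysis of Radiomic Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how sensitive radiomic features are to variability in
    tumor segmentation outlines, and how that sensitivity propagates into
    survival prediction. Provides a synthetic lesion phantom generator with
    stochastic boundary perturbation emulating plausible alternative
    segmentations, an IBSI-aligned 2D radiomic feature extractor (first-order,
    shape, GLCM, GLRLM, GLSZM, GLDM families plus wavelet-filtered variants),
    one-way random-effects intraclass correlation ICC(1) reliability scoring
    with quartile grouping and threshold signatures, Cox proportional-hazards
    survival modelling with sequential forward selection and Harrell
    concordance-index evaluation across segmentation variants under stratified
    cross-validation, and the accompanying statistical test battery (Friedman,
    Wilcoxon signed-rank, Bartlett, D'Agostino-Pearson).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Survival, FeatureExtraction, ImageAnalysis
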