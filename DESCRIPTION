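Package: radsegvar
Title: Radiomics Feature Variability Under Tumor Segmentation Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how intra-observer, inter-observer and inter-software
    tumor contouring variability propagates into CT radiomics features.
    Provides a synthetic phantom and contour-perturbation generator with
    controllable variance components, segmentation agreement metrics (Dice,
    Hausdorff, group-consensus masks), a three-category radiomics feature
    engine (shape, intensity histogram, four-direction gray-level
    co-occurrence texture), normalized-dynamic-range and Spearman redundancy
    feature reduction, ANOVA-based intraclass correlation reliability
    analysis (one-way random and two-way mixed, single measure, absolute
    agreement) with confidence intervals and four-tier classification, Lin's
    concordance correlation, and normalized per-patient feature-range
    analysis, orchestrated as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
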