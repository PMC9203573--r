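Package: ipbm
Title: Image-Perturbation-Based Reliability Assessment of Radiomic Survival Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds radiomic survival models and quantifies their reliability by
    simulating perturbed re-acquisitions of the underlying images and contours.
    Provides a synthetic CT-like phantom generator with survival outcomes, rigid
    and noise image perturbation, randomized deformable contour perturbation tuned
    to a target Dice overlap, IBSI-style radiomic feature extraction over a
    12-image filter bank (original, Laplacian-of-Gaussian, Coiflet-1 wavelet
    subbands), bootstrap log-rank relevance and correlation redundancy feature
    selection, ridge-penalized Cox modelling with recursive feature elimination,
    and feature-robustness / model-reliability quantification via the one-way
    random-effects intraclass correlation coefficient ICC(1,1) with exact
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
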