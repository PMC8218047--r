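Package: zonespect
Title: Quantitative Multi-Modal SPECT Bone Imaging with CT-Derived Tissue Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for quantitative bone SPECT
    reconstruction that incorporates CT-derived tissue "zone maps". Provides
    seeded digital ellipsoid phantoms with 140 keV attenuation maps, a
    rotation-based attenuated forward/back projector with distance-dependent
    collimator response, dual-energy-window scatter estimation, threshold-based
    five-class zone segmentation, three reconstruction variants (OSEM,
    conjugate-gradient MLEM, and zonal CG with edge-preserving zonal
    smoothing), absolute quantification to Bq/ml and body-weight SUV with
    50%-of-maximum VOI lesion statistics, reader-concordance analytics
    (confidence likelihood ratios, contingency chi-squared, intraclass
    correlation, majority-vote surrogate truth), and ROC machinery for
    SUV-based lesion classification (AUC with Hanley-McNeil and DeLong
    standard errors, Youden criterion, BCa bootstrap intervals, exact
    binomial confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    boot,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
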