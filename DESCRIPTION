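Package: rtdecide
Title: Dose-Prediction-Based Technique Selection for Breast Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-slice absolute dose distributions for tangential
    3D conformal (3D-CRT) and intensity-modulated (IMRT) breast radiotherapy
    with a 2D U-Net regressor, derives dose-volume histogram (DVH) metrics
    from the predicted volumes, and recommends the treatment technique by
    applying organ-at-risk constraints (ipsilateral lung V20Gy < 30%, heart
    V25Gy < 10%, mean heart dose < 3 Gy). Includes a synthetic thorax
    phantom cohort generator with paired analytic 3D-CRT/IMRT dose engines,
    the data-preparation pipeline (dose renormalization, body-fitting crop,
    nearest-neighbour resampling, patient-level k-fold splitting), DVH and
    isodose Dice evaluation tools, and confusion-matrix validation of the
    recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
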