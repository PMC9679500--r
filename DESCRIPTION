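Package: starchnir
Title: Chemometric Calibration of Fresh-Root Starch Content from
    Short-Wave NIR Spectra
Version: 0.1.0
Authors@R:
    person("Starchnir", "Developers", email = "starchnir@example.org",
           role = c("aut", "cre"))
Description: An end-to-end calibration pipeline for predicting cassava
    fresh-root starch content from short-wave near-infrared reflectance
    spectra (740-1070 nm, 1 nm grid). Provides spectral pretreatment
    (standard normal variate, Savitzky-Golay smoothing and derivatives,
    gap-segment derivatives), PCA-based Mahalanobis outlier screening,
    first-party partial least squares regression with cross-validated
    rank selection, radial-kernel support vector regression and random
    forest regression, genotype-grouped resampling validation with the
    CV0/CV00/CV1/CV2 genotype-by-environment schemes, a full
    prediction-quality metric suite (R2p, RMSEP, SEP, bias, RPD, RPIQ,
    CCC), VIP and permutation wavelength importance, REML variance
    components with broad-sense heritability for RCBD and alpha-lattice
    field designs, and a synthetic multi-trial field/spectra generator
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
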