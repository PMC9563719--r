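Package: starchfusion
Title: Spectral and Textural Data Fusion for Hyperspectral Prediction
    of Potato Starch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for predicting starch content of intact
    potato tubers from visible/near-infrared hyperspectral images. Provides
    ENVI-style cube input/output with white/dark reflectance calibration,
    region-of-interest mean spectra with standard normal variate (SNV)
    preprocessing, per-sample principal-component score images, gray-level
    co-occurrence matrix (GLCM) texture features, competitive adaptive
    reweighted sampling (CARS) wavelength selection, correlation-based
    texture-variable selection, low- and mid-level data fusion, and NIPALS
    partial least squares regression with cross-validated latent-variable
    selection and Rc/RMSE/RPD evaluation. A synthetic hypercube generator
    with planted spectral and textural starch signal makes the full
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
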