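Package: nspec
Title: Leaf Nitrogen Estimation from Canopy Reflectance Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Chemometric pipeline for estimating winter-wheat leaf nitrogen
    concentration (%) from visible/near-infrared canopy reflectance spectra
    (400-950 nm). Provides Savitzky-Golay smoothing, first-derivative and
    continuum-removal (convex-hull) spectral transforms, four multivariate
    calibration engines (multiple linear regression, principal component
    regression, NIPALS partial least squares, and epsilon-SVR with an RBF
    kernel) with cross-validated model-order and hyperparameter selection,
    variable-importance-in-projection (VIP) effective-wavelength selection
    with refitting on the reduced band set, and RPD-based model evaluation.
    A mechanistic synthetic canopy-spectra generator makes the whole
    workflow testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
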