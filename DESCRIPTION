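Package: hsitss
Title: Hyperspectral Imaging Chemometrics for Fruit Soluble Solids Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and mapping total soluble solids (TSS, degrees
    Brix) in dark-skinned fruit from visible/near-infrared hyperspectral
    reflectance images. Provides a seeded synthetic hypercube generator for
    end-to-end testing, white/dark reflectance calibration, band-difference
    background masking, SPXY (joint spectral-response distance) sample set
    partitioning, Random Frog selection-probability wavelength ranking, PLS1
    (NIPALS) and least-squares support-vector-machine calibration models with
    leave-one-out cross-validation and grid search, ENVI-format cube input and
    output, and pixel-wise unfold-predict-fold chemical concentration mapping
    with pseudo-colour rendering, including a bundled published 23-wavelength
    multilinear TSS model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
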