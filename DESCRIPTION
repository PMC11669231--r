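Package: chemocal
Title: Chemometric Calibration of Overlapping UV Spectra for Quaternary Drug Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Multivariate spectrophotometric calibration workflow for
    quantifying antipyrine, benzocaine, antipyrine impurity A and
    p-aminobenzoic acid in quaternary mixtures with strongly overlapping
    UV spectra. Provides a Brereton-style multilevel calibration design,
    a Beer-Lambert spectra simulator with Gaussian absorption bands,
    NIPALS partial least squares with leave-one-out cross-validation and
    F-test latent-variable selection, a feedforward neural-network
    regressor trained by backpropagation, constrained multivariate curve
    resolution by alternating least squares, validation figures of merit
    (recoveries, SEP, RMSEP, LOD, LOQ), two-sample t and F method
    comparison, and an analytical Eco-scale greenness calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
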