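Package: grapeSpec
Title: Vis/NIR Multispectral Calibration of Soluble Solids Content in Wine
    Grapes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Data optimization and calibration chain for predicting the
    soluble solids content (SSC, degrees Brix) of wine grapes from 18-band
    visible/near-infrared reflectance spectra acquired with low-cost
    multispectral sensors. Provides an S4 container for banded spectra built
    on SummarizedExperiment, reflectance calibration and replicate averaging,
    Monte-Carlo resampling and PCA/Hotelling T-squared outlier screening,
    eight spectral preprocessing methods (derivatives, scatter correction,
    smoothing, scaling), characteristic-wavelength selection by uninformative
    variable elimination (UVE) and the successive projections algorithm
    (SPA), SPXY sample-set partitioning, NIPALS partial least squares
    regression, and a statistical generator of SSC-linked synthetic spectra
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, signal, jsonlite, yaml
Suggests: testthat (>= 3.0.0), mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
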