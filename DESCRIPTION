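Package: ramanviability
Title: Cell Viability Estimation from Single-Cell Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for label-free cell-viability assays based on
    single-cell Raman spectroscopy. Provides a synthetic-data generator for
    drug-treated cell populations (macromolecular band mixtures, dose-scaled
    fluorescence background, water background, gain fluctuation, detector
    noise, cosmic spikes, empty detections), wavelength and intensity
    calibration against reference-band and calibration-lamp spectra, a
    spectral cleanup chain (cosmic-spike removal, third-order extended
    multiplicative signal correction, Savitzky-Golay smoothing, area
    normalization, region selection, empty-spectrum rejection), PCA-SVM
    classification of viable versus non-viable cells, mixed-population
    viability-fraction prediction, and log-logistic dose-response (IC50)
    fitting with comparison against a reference viability assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
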