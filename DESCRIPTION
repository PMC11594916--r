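Package: lcophys
Title: Photophysics of Amyloid-Binding Fluorescent Ligands: Decay Fitting,
    Binding Models, Spectra and FLIM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative photophysics toolkit for luminescent conjugated
    oligothiophene (LCO) probes binding amyloid fibrils. Implements
    iterative-reconvolution biexponential fitting of time-correlated
    single photon counting (TCSPC) decay histograms with amplitude- and
    intensity-weighted mean lifetimes; relative quantum-yield
    determination by the dilution-series gradient method; one- and
    two-site ligand-depletion equilibrium binding models with per-species
    brightness, curve simulation and fitting; emission-spectrum blank
    subtraction, area normalization and peak finding; and fluorescence
    lifetime imaging (FLIM) region-of-interest analysis with Gaussian
    lifetime-distribution fitting. Seeded synthetic-data generators
    emulate every input class so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
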