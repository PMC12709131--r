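Package: soxdosim
Title: Singlet Oxygen Luminescence and Explicit Dosimetry for Photodynamic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Type II photodynamic therapy (PDT) dosimetry in liquid
    phantoms. Implements multispectral singlet oxygen luminescence dosimetry
    (MSOLD): spectral unmixing of the 1270 nm singlet oxygen emission band
    from photosensitizer phosphorescence and laser background by
    singular-value-decomposition least squares, quench-difference extraction,
    and fluorescence-window photobleaching tracking. Implements the singlet
    oxygen explicit dosimetry (SOED) macroscopic kinetic model of
    photosensitizer photobleaching, oxygen consumption and cumulative reacted
    singlet oxygen, integrated over an irradiation protocol. Provides a
    synthetic spectrometer-output generator driven by the kinetic model with
    full ground truth, linear-regression correlation of MSOLD against SOED,
    packaged optical-property correction factors with bilinear interpolation,
    and a two-stage Monte Carlo photon transport model of luminescence
    detection in a semi-infinite turbid medium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
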