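Package: derivspec
Title: Zero-Crossing Derivative Spectrophotometry for Multicomponent
    UV-Vis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying co-formulated drugs from strongly
    overlapped UV-Vis absorption spectra by derivative spectrophotometry
    with the zero-crossing technique.  Computes first- to fourth-order
    derivative spectra (centred finite differences or Savitzky-Golay
    smoothing-differentiation), locates zero-crossing wavelengths and
    selects interference-free working wavelengths, fits and aggregates
    replicate calibration curves with LOD/LOQ estimation, evaluates
    precision, accuracy, standard-addition recovery and method-comparison
    statistics (paired t, variance-ratio F), simulates Beer-Lambert
    three-component mixture spectra with instrument noise, and
    back-calculates tablet content through dilution schemes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
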