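Package: glycosc
Title: Kinetic Modelling and Spectral Analysis of Yeast Glycolytic
    Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying NADH-mediated glycolytic oscillations in
    Saccharomyces cerevisiae. Implements the nine-state Wolf kinetic model
    of anaerobic glycolysis with stiff ODE integration, limit-cycle
    amplitude and period extraction with parabolic peak interpolation,
    normalized finite-difference parameter sensitivities of amplitude and
    period, in-silico GAPDH activity-scaling experiments, discrete Fourier
    analysis of NADH fluorescence traces, and a protocol-faithful synthetic
    trace generator with strain-phenotype presets for closed-loop
    validation of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
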