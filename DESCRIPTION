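Package: sgnmech
Title: Phase-Locking Statistics and Mechanotransduction Curve Fits for
    Spiral Ganglion Neuron Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for patch-clamp studies of intrinsically
    mechanosensitive auditory neurons. Provides spike detection from
    voltage traces, circular statistics for phase-locked spike trains
    (vector strength, Rayleigh uniformity test, cycle histograms,
    peak-splitting detection, polar resultant summaries across relative
    stimulus phase angles), biophysical curve fitting (Boltzmann
    mechanotransduction activation, Hill dose-response block,
    bi-exponential current decay, linear I-V regression), a synthetic-data
    generator for every input the pipeline consumes, and a leaky
    integrate-and-fire neuron simulator with a mechanically activated
    conductance for combined current and displacement stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
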