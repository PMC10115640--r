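Package: cftrgate
Title: Kinetic Modelling and Single-Molecule Analysis of CFTR Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the ATP-driven gating cycle of the CFTR
    anion channel. Implements a nine-state continuous-time Markov model of
    the gating cycle (ATP binding, NBD dimerization, pore opening, flicker
    closures, ATP hydrolysis and nucleotide exchange), with exact
    stationary and relaxation solutions, Gillespie simulation under
    piecewise-constant ATP protocols, and constrained calibration of rate
    constants against experimental observables. A synthetic-data module
    renders simulated trajectories into camera-sampled smFRET fluorescence
    traces (frame integration, photobleaching, blinking, intensity noise)
    and low-pass-filtered single-channel current traces. The analysis
    chain covers FRET efficiency computation, trace quality control,
    segmental k-means idealization, dwell-time survival analysis, Hill
    dose-response fits, exponential relaxation fits and allosteric
    coupling summaries, plus a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
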