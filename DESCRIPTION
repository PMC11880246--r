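Package: bilayerlab
Title: Single-Channel Analysis for Planar Lipid Bilayer Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analyzing single-channel current recordings from
    planar lipid bilayer experiments: threshold idealization of traces into
    open/closed events with a fixed dead time, open-probability estimation,
    all-point amplitude histograms with two-component Gaussian fits,
    current-voltage (I-V) slope-conductance and reversal-potential
    estimation, and Nernst / Goldman-Hodgkin-Katz (GHK) reversal-potential
    solvers with closed-form permeability-ratio inversion, including a
    divalent-cation extension. A seeded two-state Markov gating simulator
    renders bilayer-like traces (exponential dwell times, conductance-set
    unitary current, Gaussian noise, low-pass filtering) for validation and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
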