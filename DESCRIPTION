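Package: vdacgate
Title: Single-Channel Gating Analysis for VDAC Planar Lipid Bilayer Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel current recordings of the
    voltage-dependent anion channel (VDAC) reconstituted in planar lipid
    bilayers. Provides a semi-Markov gating simulator with per-variant channel
    presets, change-point idealization of current traces into conductance
    events, through-origin Ohm-plot conductance estimation, nested two-stage
    Gaussian-mixture decomposition of closed-state amplitude histograms into
    sub-states, dwell-time statistics with fold-change comparisons,
    polarity-asymmetric gating detection, and summary-statistics Welch t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
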