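Package: dualosc
Title: Deterministic Modelling of the AraC/LacI Dual-Feedback Oscillator
    with Downstream Reporter Load
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic ordinary-differential-equation model of the
    AraC/LacI dual-feedback (Smolen-type) genetic oscillator with three
    alternative downstream GFP reporter configurations (lac/ara promoter,
    lac promoter, lac promoter plus AraC decoy site) and independently
    toggleable retroactivity (binding-site titration of regulatory
    proteins) and protease sharing (competition of SsrA-tagged proteins
    for ClpXP degradation). Promoter occupancy is resolved at the
    microstate level, including single-tetramer LacI DNA looping.
    Includes Newton-Raphson equilibrium finding with eigenvalue and
    Routh-Hurwitz stability classification, two-inducer
    (arabinose x IPTG) phase-diagram sweeps with amplitude and period
    maps, an oscillation bottom-counting scorer for fluorescence
    time courses, and a synthetic microscopy-trace generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
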