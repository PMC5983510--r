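Package: g0switch
Title: Deterministic Model of the Reversible Quiescence-Proliferation Transition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation model of the coupled Rb-E2F and
    APC/C-Cdh1-Emi1 bistable switches that control entry into and exit from
    quiescence in mammalian cells. Provides stiff time-course simulation with
    timed parameter perturbations, quiescent-state initialisation, event-time
    extraction and commitment probing; steady-state solving with stability
    analysis, pseudo-arclength continuation with saddle-node detection,
    two-parameter fold tracking and threshold-sensitivity scans; named
    scenario presets reproducing the model's canonical computational
    experiments; and plain-text configuration, CSV trajectory and XPPAUT
    .dat import/export utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
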