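Package: motifsynergy
Title: Synergism of Paired Parameter Perturbations in Signaling Network Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic ordinary-differential-equation models of ten
    three-node signaling motifs (converging pathways with feed-forward,
    feedback and auto-regulatory variations) and of a two-gene CREB1/CREB2
    bistable switch, together with a paired-parameter perturbation protocol
    that quantifies nonlinear-blending (NB) and additive synergism of
    concurrent parameter changes. Provides a fixed-step fourth-order
    Runge-Kutta integrator, pre-stimulus equilibration, square-pulse and
    pulse-train stimulus protocols, allocation-grid blending curves under a
    fixed perturbation budget, degrees and classifications of NB and
    additive synergism, all-pairs sweeps with threshold summaries and
    histograms, stimulus dose-effect scans, and sensitivity-analysis
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
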