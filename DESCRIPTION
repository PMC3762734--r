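Package: mfwave
Title: Myocyte-Fibroblast Composites and Spiral-Wave Dynamics in Human
    Ventricular Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis suite for cardiac myocyte-fibroblast
    (MF) electrophysiology.  Couples the ten Tusscher-Noble-Noble-Panfilov
    (2004) human ventricular epicardial ionic model to passive RC
    fibroblasts, both as single MF composites (action-potential morphology,
    autorhythmicity, coupled-vs-uncoupled deltas) and as a two-dimensional
    bilayer monodomain tissue with zero-, one-, and two-sided intercellular
    couplings.  Includes plane-wave conduction-velocity protocols, S1-S2
    parallel-field spiral initiation, MF-composite inhomogeneities,
    low-amplitude mesh-based spiral control, sodium-current spiral-tip
    tracking, inter-beat-interval and power-spectrum analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
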