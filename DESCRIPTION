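Package: primingscreen
Title: Detection and Mechanistic Classification of Cellular Priming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and mechanistically classifying cellular
    priming (preconditioning), the amplified response to a high-dose
    stimulus after pretreatment with a sub-threshold low dose. Provides a
    generic three-node signaling-motif simulator with a two-stage
    Metropolis search that recovers the three canonical priming
    mechanisms (pathway synergy, activator induction, suppressor
    deactivation); a time-course expression screening pipeline
    (detection-call and fold-change filtering, Welch tests with
    false-discovery-rate correction, dynamics classes, readout
    identification, reshuffling analysis) that assigns genes to
    mechanism roles; a matcher that maps role-annotated genes onto signed
    regulatory networks to emit candidate priming motifs; a detailed
    interferon-gamma Jak/STAT kinetic model with a prime-wash-restimulate
    protocol; and a seeded synthetic-data generator emulating a
    six-condition, three-pool macrophage microarray design so every
    pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
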