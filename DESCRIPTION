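Package: retromra
Title: Modular Response Analysis for Signaling Networks with Enzyme
    Sequestration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Perturbation-based reconstruction of connections between
    signaling modules when inter-modular enzyme-substrate complexes
    sequester proteins across module boundaries.  Simulates steady-state
    responses of mass-action kinase-cascade models to parameter
    perturbations, infers connection (local response) coefficients by
    Modular Response Analysis (MRA), and restores modular insulation by
    redefining communicating species as weighted sums of free active
    enzymes and inter-modular complexes.  The weight that nullifies
    sequestration-induced (retroactive) connections discriminates them
    from regulatory connections.  Ships the two-module MEK/ERK benchmark
    and configurable three-tier cascades with regulatory feedback.
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
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
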