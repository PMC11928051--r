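Package: hoverscale
Title: Allometric Scaling Analysis of Normal Hovering Flight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the aerodynamic scaling analysis of normal hovering
    animals (insects and hummingbirds). Computes dimensional and
    nondimensional hover parameters (wing-tip velocity, reduced frequency,
    cycle-averaged lift coefficient, Reynolds number) from morphology and
    kinematics, derives theoretical allometric exponents by exact rational
    arithmetic -- including the -1/6 flapping-frequency law obtained from a
    body-attitude constraint -- and fits empirical power-law allometries by
    ordinary and phylogenetic generalized least squares with Pagel's lambda.
    A synthetic-clade generator produces phylogenies and observation tables
    with known allometric structure so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    jsonlite,
    nlme,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
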