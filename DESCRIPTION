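Package: phosflux
Title: Phosphatase Substrate-Preference Kinetics and Dynamic Flux
    Simulation of GlcNAc Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Michaelis-Menten analysis of phosphatase initial-velocity
    assays and kcat/Km substrate-preference panels, together with a
    kinetic model of N-acetylglucosamine (GlcNAc) biosynthesis in an
    engineered Escherichia coli chassis: eight metabolite states, twelve
    Michaelis-Menten reactions, Hill-regulated phosphatase expression
    driven by a GlcNAc6P-responsive biosensor, and phosphosugar-pressure
    inhibition of glucose uptake. Includes seeded Monte-Carlo parameter
    sampling for ensemble simulation across phosphatase variants,
    paired variant comparisons, and synthetic-data generators for
    velocity assays and fluorescence plates so every stage is testable
    without external data. Ships the measured kcat/Km panel for
    phosphatase BT4131 and its engineered variants as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
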