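Package: wolbinvade
Title: Wolbachia Invasion Dynamics in Stage-Structured Mosquito Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the establishment of Wolbachia (wAlbB strain)
    infection in Anopheles mosquito populations with an eight-compartment,
    two-sex, stage-structured ordinary differential equation model. The model
    tracks eggs, larvae/pupae, and adult males and females by infection
    status, and accounts for maternal transmission, cytoplasmic
    incompatibility, fitness costs of infection, and a logistic larval
    carrying capacity. The package provides the closed-form analytic layer
    (next-generation numbers, basic reproductive number, disease-free,
    complete-infection and coexistence equilibria, and the bistability
    threshold), eigenvalue-based stability classification and bifurcation
    scans, local elasticity-based sensitivity analysis, an intervention
    engine for pre-release mitigation and batched field releases of infected
    adults, and seasonal carrying-capacity forcing fitted to monthly
    rainfall.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
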