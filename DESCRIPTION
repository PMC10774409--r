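Package: warmsoil
Title: Microbial Carbon-Cycling Analysis for Warming x Management Field Experiments
Version: 0.1.0
Authors@R:
    person("Warmsoil", "Developers", email = "maintainer@warmsoil.dev",
           role = c("aut", "cre"))
Description: Tools to analyse decade-long warming by agricultural-management
    field experiments on soil microbial carbon cycling: microbial carbon use
    efficiency from 18O-H2O incubations, microbial necromass carbon from
    amino-sugar biomarkers, root exudation carbon, community temporal turnover
    via moving-window time-decay relationships, warming-induced community
    divergence trajectories, and Cohen's d effect-size trajectories with OLS
    and standardized major axis trends. Includes a fully seeded synthetic-data
    generator with exported ground truth so every stage of the pipeline can be
    validated without field data, plus a command-line pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
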