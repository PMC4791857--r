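Package: plovermeta
Title: Multistate Mark-Recapture and Flow-Disturbance Metapopulation Viability
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing survival and dispersal of birds in a
    disturbance-driven river metapopulation and for projecting its long-term
    viability. Provides an Arnason-Schwarz multistate mark-recapture
    likelihood with design-matrix covariate models (age, subpopulation, year,
    hatch date, banding age, reproductive success, inter-site distance, and
    high-flow indicator variables), quasi-likelihood model selection (QAICc),
    model averaging, and Wald inference; an individual-based stochastic
    metapopulation viability simulator in which high-flow events destroy and
    then create nesting habitat, driving carrying-capacity dynamics,
    flow-state-dependent demography and dispersal; and a synthetic-data
    generator that reproduces the three-subpopulation piping plover study
    design so the whole analysis is runnable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
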