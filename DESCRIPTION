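Package: hebbca
Title: Hebbian Cell-Assembly Networks of Fronto-Temporal Cortex and Their
    Spontaneous Ignition Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a six-area rate-based model of frontal and temporal
    cortical areas (primary, secondary and higher-association sensory and
    motor areas) built from graded-response leaky-integrator cells with
    neuronal adaptation, uniform membrane noise, local lateral inhibition and
    area-global inhibitory feedback.  Sparse, patchy, topographic within- and
    between-area projections are grown at random and shaped by a discretised
    Artola-Broecher-Singer Hebbian learning rule during repeated paired
    stimulation of sensory and motor patterns, leading to distributed
    sensorimotor cell assemblies.  Provides the full analysis pipeline for
    spontaneous (noise-driven) assembly ignition: probe-based cell-assembly
    membership, ignition-event detection, event-aligned average spontaneous
    ignition (ASI) traces, baseline alignment, and per-time-step
    repeated-measures ANOVA with planned comparisons across area centrality
    and frontality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
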