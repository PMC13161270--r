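Package: readyset
Title: Movement-Readiness Potentials and Visuomotor Adaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cognitive-motor integration
    studies that pair a visuomotor rotation reaching task with movement-locked
    EEG. Generates synthetic cohorts (state-space motor learner, minimum-jerk
    reach trajectories, movement-readiness-potential templates with 1/f noise,
    NASA-TLX responses), computes the behavioral measures (response time, peak
    velocity with its cleaning cascade, circular hand angle, early/late stage
    summaries), extracts readiness potential, negative slope and motor
    potential component amplitudes from movement-locked epochs (baseline
    correction, threshold-based trial rejection, region-of-interest averaging,
    trial-half splitting), scores raw NASA-TLX workload and its task- and
    behavior-related subscales, and runs the study's statistical layer:
    pooled t tests with Cohen's d, linear mixed models with Satterthwaite
    degrees of freedom, and Sidak-adjusted estimated-marginal-mean contrasts.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
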