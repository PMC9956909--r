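Package: retscreen
Title: High-Throughput Phenotyping of Mouse Vision from OCT and ERG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for high-throughput screening of mouse
    retinal structure and function. Measures full-field electroretinogram
    (ERG) a- and b-wave amplitudes and implicit times from flash-response
    sweep recordings, segments retinal boundaries (ILM, OPL, ELM, Bruch's
    membrane) on optical coherence tomography (OCT) B-scans, builds layer
    thickness maps summarized on an optic-disc-centered quadrant and ring
    grid, and provides the cohort statistics used in knockout and aging
    comparisons (Welch tests from summary statistics, two-way ANOVA with
    Tukey or Sidak post-hoc comparisons). A synthetic-data layer simulates
    stimulus protocols, ERG sweep sets with known ground-truth wave
    parameters, layered retinal phantoms with ground-truth boundaries and
    simulated cohorts, so the whole pipeline is testable end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    tiff,
    jsonlite,
    yaml,
    readr,
    zoo,
    car,
    emmeans,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
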