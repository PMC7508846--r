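Package: pretre
Title: Stochastic Simulation of Polycomb/Trithorax Response Element Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a bistable nucleosome-modification array (a
    Polycomb/Trithorax response element, PRE/TRE) bidirectionally coupled
    to a transcription-factor binding-site promoter over the Drosophila
    developmental cell-cycle schedule. Ships built-in scenarios for
    epigenetic memory of silencing and activation, Polycomb-mutant
    derepression, developmental accumulation of chromatin modifications,
    and a spatial eye-disc model contrasting stable memory against
    fine-tuning and position-effect variegation. Includes an exact
    small-system Markov-chain oracle for validating the stochastic
    update rules, ensemble statistics (memory score, variegation index,
    derepression time, gradient profiles), parameter-grid scans, and a
    command-line interface for reproducible seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
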