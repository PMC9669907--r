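Package: herdcomm
Title: Team Coordination and Communication Dynamics in a Cooperative
    Herding Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying team coordination in a
    cooperative multiplayer herding task. Provides a seeded agent-based
    simulator of a desert herding game (evasive Brownian targets,
    repulsion-driven corralling, a 2x2x2 task design crossing target
    number, fog visibility and a late-spawn perturbation), a coupled
    multi-speaker speech generator whose talk-time statistics follow
    condition- and role-dependent targets, categorical recurrence
    quantification (percent recurrence and percent determinism at
    operator, ground-player and team levels), alpha-shape search-area
    overlap, per-trial performance metrics, and the study's inferential
    machinery: 2x2x2 repeated-measures ANOVA with Greenhouse-Geisser
    and Bonferroni corrections, partial eta squared, and random-intercept
    mixed regression with Cohen's f squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    interp,
    polyclip,
    igraph,
    lme4,
    stats,
    grDevices,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    sp,
    knitr
Config/testthat/edition: 3
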