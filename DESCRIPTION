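Package: batkit
Title: Scoring and Group-Level Analysis for the Beat Alignment Test
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the Beat Alignment Test (BAT), a two-part assessment
    of musical beat processing: judging whether beeps overlaid on music fall
    on the beat, and tapping in time with the beat. The package constructs
    perturbed click-track stimuli (phase and period shifts), scores tapping
    records for phase-matching asynchrony, tempo-matching coefficient of
    deviation and stimulus-independent coefficient of variation, scores
    perception responses as percent correct, and runs the group-level
    analyses used with such batteries: factorial ANOVA with Type III sums
    of squares and partial eta squared, simple main effects, Bonferroni
    pairwise comparisons, Welch t tests, age-score linear models, and
    Bayesian model-comparison bookkeeping (posterior model probabilities,
    BF_M, evidence bands, and BIC-approximated Bayes factors). A synthetic
    cohort simulator with parametric perceiver and tapper models provides
    ground-truth data for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
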