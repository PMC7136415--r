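Package: actimark
Title: Two-State Markov Modelling of Rodent Rest-Activity Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probabilistic analysis of binned actigraphy records
    from rodents housed under light-dark (T-cycle) or constant-darkness
    conditions. Activity counts are encoded into binary rest/activity state
    sequences and modelled as a two-state Markov chain whose transition
    probabilities (alpha: rest to activity; beta: activity to rest) switch
    between the day and night phases of the circadian cycle. The package
    estimates phase-conditional transition probabilities and the derived
    mean bout lengths and activity fractions, labels circadian phase from
    light flags or by cosinor fitting of a free-running period, extracts
    and summarises bouts, simulates single animals and whole cohorts from
    fitted or published parameters, runs model diagnostics (split-half
    stability, a conditional mutual information check of the Markov
    property, observed-versus-geometric bout length distributions), tests
    for ultradian and circadian rhythmicity with the Enright chi-squared
    periodogram under Bonferroni control, and produces cohort-level
    fold-change summaries with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
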