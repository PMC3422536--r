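Package: sdtyesno
Title: Signal Detection Theory Simulation and Analysis for Yes/No
    Psychoacoustic Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing yes/no detection behaviour
    under an equal-variance signal detection theory (SDT) observer model
    with decision-related components: a block-level criterion bias,
    trial-by-trial criterion shifts driven by the previous two responses,
    an attentional guess rate, and correction trials. Implements the three
    classical psychoacoustic data-collection procedures (Method of Limits,
    Method of Constant Stimuli, adaptive up-down tracking), psychometric
    function fitting and 71% threshold estimation from P(c)max,
    sequential-dependency (choice-history) analysis with Holm-Bonferroni
    corrected chi-squared tests, a staged model-fitting procedure for
    recovering observer parameters from hit and false-alarm rates, and a
    deterministic reward-optimality analysis of the decision criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
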