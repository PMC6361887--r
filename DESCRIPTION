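Package: magnosim
Title: Simulation and Analysis of Magnocellular Visual-Motion Training Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse behavioural intervention studies
    of visual magnocellular function in children with reading difficulties.
    Implements the weighted up-down adaptive staircase used for coherent
    motion (random dot kinematogram) thresholds, closed-form and mechanistic
    simulated observers, RDK stimulus generation, engines for the training
    tasks (digit counting, dot counting, feedback RDK, saccade-cycle
    scoring), a synthetic two-group longitudinal cohort generator with an
    inclusion screen, and a from-formula mixed-design repeated-measures
    ANOVA with Mauchly's sphericity test, Greenhouse-Geisser correction,
    partial eta squared, and follow-up t and Mann-Whitney tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
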