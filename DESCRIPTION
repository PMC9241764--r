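Package: npmdyn
Title: Longitudinal Dynamics of Nasopharyngeal Microbiome Profile Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for longitudinal nasopharyngeal microbiome
    cohorts profiled at genus level. Classifies samples into microbiome
    profile groups (MPGs) by dominant genus, tests the temporal stability of
    each MPG against a random-transition null (observed stable-transition
    frequency with bootstrap confidence intervals versus the squared
    state-frequency expectation), calls stable colonization per subject,
    models diversity and genus-abundance trends with linear mixed-effects
    models, and summarises community shifts across the pre-exacerbation,
    exacerbation and post-exacerbation phases. Includes a Dirichlet-
    multinomial simulator of longitudinal compositional count data with
    known ground truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    permute,
    withr
Config/testthat/edition: 3
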