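Package: complnet
Title: Bayesian Network Analysis of Perioperative Complication Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the joint occurrence of binary perioperative
    complications as a discrete Bayesian network. Provides cohort ingestion and
    validation for patient-level 0/1 complication matrices, descriptive
    co-occurrence statistics (marginal frequency and mortality tables, phi
    coefficient matrices, complication-multiplicity histograms, collinearity
    diagnostics), score-based structure learning by hill climbing with a BIC
    score and an arc blacklist, bootstrap model averaging with arc strength and
    direction probabilities, maximum-likelihood estimation of conditional
    probability tables, exact conditional-probability queries by variable
    elimination, Markov-blanket identification of critical complications, and a
    seeded synthetic-cohort generator driven by a configurable ground-truth
    network, so the whole pipeline can be exercised and validated without
    registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
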