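Package: hs2cea
Title: Economic Evaluation of the HS2 Referral Intervention for Recurrent
    Hypoglycaemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage decision-tree model of recurrent hypoglycaemia in
    the fortnight following an initial attack resolved at scene by emergency
    medical services, comparing the leaflet-based "'Hypos' can strike twice"
    (HS2) referral intervention against standard care from the perspective of
    the UK NHS. Provides baseline cost-effectiveness and cost-utility
    analyses, calibration of severe-recurrence transition probabilities to
    observed repeat-attendance rates, one-way and probabilistic sensitivity
    analyses on the cost-effectiveness plane, an absorbing-Markov
    cost-minimisation extension over fortnightly cycles, and a synthetic
    episode-level trial generator for end-to-end testing of every estimator
    the model consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
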