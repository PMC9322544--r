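Package: painchoice
Title: Simulation and Analysis of Probabilistic Pain Decision-Making in Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a dyadic probabilistic pain-management task in which a
    deciding agent views cues predicting a pain intensity with a stated
    probability, chooses between a gamble (50% chance of avoiding pain
    altogether) and a sure option (pain intensity reduced by one level), bids
    on the chosen treatment in a sealed-bid auction against a hidden random
    reserve price, and finally rates the delivered pain. Provides the
    mean-variance formalization of expected pain and pain risk, the auction
    and outcome-resolution mechanics, a simulator of the laser-energy pain
    calibration procedure, a synthetic-cohort generator with subject-level
    random intercepts, and the full statistical pipeline: descriptives,
    per-target gamble-proportion fits, maximum-likelihood estimation of
    Arrow-Pratt risk aversion from choices, three mixed models (binomial and
    Gaussian) with subject random intercepts, and a parameter-recovery
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
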