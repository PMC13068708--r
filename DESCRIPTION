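Package: typeBsim
Title: Stimulus-Order Effects in Duration Discrimination: Models, Designs and Estimation
Version: 1.0.0
Authors@R: person("Jonas", "Richter", email = "jrichter@example.org",
    role = c("aut", "cre"))
Description: Trial-by-trial simulation of two-interval duration discrimination
    under three observer models (Thurstonian difference model, internal
    reference model with trial-wise reference updating, and the sensation
    weighting model), together with the designs and analysis chain used to
    measure stimulus-order effects on discrimination sensitivity (Type B
    effects): method-of-constant-stimuli trial sequences, weighted up-down
    adaptive staircases with bias-prone dialect options, non-parametric
    Spearman-Kaerber estimation of PSE, DL and Weber fractions, pool-adjacent-
    violators monotonization, repeated-measures and mixed ANOVAs with
    Mauchly/Greenhouse-Geisser handling, noncentral-F power for two-level
    within-subject designs, full synthetic cohort generation with
    flat-function exclusion, a staircase-bias simulation study, and
    grid-search recovery of the reference-updating weight.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
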