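Package: wmhpower
Title: Sample Size and Power for Trials Using White Matter Hyperintensity
    Progression as an Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sample-size calculus for randomised trials that use cerebral
    white matter hyperintensity (WMH) progression at one year as an
    intermediate outcome: the two-group normal formula with covariate
    (R-squared) deflation for WMH-volume outcomes, Whitehead's
    proportional-odds formula with covariate-adjustment multipliers and
    odds-ratio sensitivity sweeps for ordinal Fazekas-score outcomes, the
    tie-corrected Noether rank-sum design, and compounding dropout
    inflation. Includes a calibrated synthetic mild-stroke cohort
    generator with informative dropout, the matching analysis stage
    (linear and ordinal regressions, variance inflation factors,
    completer comparisons), and a seeded Monte-Carlo power-verification
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    car
Config/testthat/edition: 3
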