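Package: dwpaired
Title: Disability Weight Estimation from Paired Comparison and Companion
    Valuation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates disability weights for health states from stated-
    preference survey data. The core model is a Thurstone-style probit
    regression on paired-comparison choices with 'being dead' as the
    reference category and 'full health' and 'being dead' as anchor
    states, so that weights are obtained without a cardinal trade-off
    method. Companion estimators cover a hybrid model that links
    paired-comparison probabilities to population-health-equivalence
    ladder responses through interval regression, and direct visual
    analogue scale and standard gamble models based on disutilities.
    Includes a seeded survey simulator for all four instruments, holdout
    validation of the choice model, and an evaluation layer (Pearson
    correlations against a reference set, severity-bin distributions,
    extremes and utility comparisons) together with a packaged reference
    table of published estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    survival,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
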