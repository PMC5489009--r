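Package: pmvcal
Title: Thermal Comfort Prediction with Calibrated Metabolic Rates and
    Outdoor-Climate Extensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing thermal-sensation field surveys with the
    Fanger heat-balance (PMV/PPD) model. Implements the forward PMV engine
    with the iterative clothing-surface-temperature solution, subpopulation
    basal/resting metabolic rate prediction from anthropometrics
    (Harris-Benedict equations revised by Roza and Shizgal, DuBois body
    surface area), per-respondent inverse calibration of the metabolic rate
    against thermal sensation votes, the running mean outdoor temperature
    (RMOT), affine model extensions driven by RMOT and thermal preference,
    subgroup comparison statistics, and a synthetic survey-campaign
    generator with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
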