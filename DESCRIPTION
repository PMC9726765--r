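Package: wahe
Title: Well-Being Adjusted Health Expectancy and Validation of Summary
    Measures of Population Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates well-being adjusted health expectancy (WAHE), a
    summary measure of population health that weights life-table person-years
    by health-state well-being weights derived from survey respondents who
    experience each state. Provides ordered-probit estimation of
    health-related well-being weights from life-satisfaction microdata with
    threshold-range standardization to the [0,1] full-health-equivalent
    scale, Sullivan-method computation of life expectancy, health expectancy
    and WAHE from period life tables and survey-weighted health-state
    prevalence, and a validation battery for comparing summary measures
    across populations: Spearman rank concordance, Bland-Altman agreement
    with trend-adjusted limits, and two-way mixed-effects consistency
    intraclass correlation with leave-one-out reliability deltas. Includes a
    synthetic microdata, life-table and measure-panel generator with known
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
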