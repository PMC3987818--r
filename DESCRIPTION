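Package: smokesae
Title: Small Area Estimation of County Cigarette Smoking Prevalence
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based small area estimation of county-level cigarette
    smoking prevalence from telephone-survey microdata in the style of the
    Behavioral Risk Factor Surveillance System (BRFSS). Fits sex-stratified
    hierarchical logistic mixed-effects models with nested state and county
    random intercepts and time slopes, post-stratifies predictions to county
    demographic composition, age-standardizes to a fixed standard population,
    propagates uncertainty through simulation draws, corrects the pre-2011
    landline-frame series for wireless-only coverage bias via a linear ramp
    anchored at 2000 and 2011, and validates models against design-weighted
    gold-standard county estimates using Lin's concordance correlation
    coefficient and root mean squared error on sampled-down data. Includes a
    synthetic survey-data generator with a known ground truth for
    parameter-recovery testing, and trend analytics (annualized rates of
    change, significance flags, within-state gaps, sex gaps, income-quintile
    summaries, and county rank uncertainty).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
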