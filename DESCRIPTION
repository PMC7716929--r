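Package: retscreen
Title: Risk-Based Variable-Interval Retinopathy Screening: Trial Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying individualised, risk-based screening intervals
    in diabetic retinopathy screening programmes. Implements a covariate-dependent
    continuous-time Markov multi-state risk-calculation engine with 6/12/24-month
    interval allocation against a 2.5% screen-positive risk threshold; a synthetic
    cohort generator and two-arm randomised trial simulator (stratified permuted-block
    randomisation, attendance behaviour, interval reassignment, withdrawals);
    equivalence and non-inferiority safety analysis with Wilson and Newcombe score
    intervals and multiple imputation with Rubin pooling; and within-trial
    cost-effectiveness analysis (QALYs by area under the utility curve,
    baseline-adjusted incremental estimates with bias-corrected bootstrap
    confidence intervals, seemingly unrelated regressions across imputed sets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
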