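Package: moodcast
Title: Daily Estimates of Clinical Severity in Bipolar Disorder from
    Smartphone Self-Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates daily clinical severity ratings (Hamilton Depression
    Rating Scale and Young Mania Rating Scale totals and item-1 scores) from
    smartphone-based self-assessments of patients with bipolar disorder,
    using a hierarchical Bayesian regression with partial pooling across
    individuals. Provides a synthetic-cohort simulator with the structure of
    the MONARCA II smartphone-monitoring study, feature engineering for the
    self-assessment items (mood/sleep sign splits, medicine dummy coding,
    range normalisation), pooled and separate naive-mean, ridge and
    gradient-boosted-tree baselines, hold-one-clinical-evaluation-per-subject
    cross-validation with predicted R-squared and RMSE, posterior-based
    variable importance, and daily relapse-risk scores from posterior
    predictive exceedance probabilities evaluated by ROC/AUC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    glmnet,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
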