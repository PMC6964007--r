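Package: jiarisk
Title: Risk Prediction Models for Juvenile Idiopathic Arthritis and
    Their External Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the published Canadian and Nordic logistic risk
    calculators for poor prognosis in juvenile idiopathic arthritis
    (non-achievement of remission, severe disease course, functional
    disability) together with the external-validation machinery used to
    port a model between cohorts: multiple imputation by chained
    equations, un-tuned evaluation with a tie-aware concordance index and
    DeLong standard errors, fine-tuning of coefficients with
    leave-one-out cross-validated C-indices, bootstrap-nested
    cross-validation (BCCV) standard errors, bootstrap coefficient
    standard errors, and Rubin's-rules pooling across imputations.  A
    synthetic inception-cohort generator emulating the statistical
    structure of such studies makes every stage testable without
    access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
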