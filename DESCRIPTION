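Package: validmi
Title: Range Restriction Corrections for Dichotomous Criteria via
    Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating the predictive validity of selection
    procedures and the base rate of success when the criterion variable is
    dichotomous and observed only for selected applicants (the range
    restriction problem). Implements Thorndike's Case-2 and Case-3
    correction formulas, a missing-data correction that multiply imputes
    the binary criterion with Bayesian logistic regression and pools point
    estimates, point-biserial and biserial correlation estimators,
    synthetic applicant-population generators for direct and indirect
    selection with naturally or artificially dichotomous criteria, and a
    Monte Carlo evaluation framework reporting mean error, root mean
    square error, and F-ratio precision comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
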