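Package: ageprop
Title: Testing the Proportionality of Stroke Risk Factors with Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a three-step framework for testing whether the
    contribution of a risk factor to short-window (e.g., five-year)
    ischemic-stroke risk is proportional to age. Step 1 fits a separate
    single-variable logistic regression per risk factor and age group;
    step 2 tests coefficient equality across age groups with a z-test on
    the pair with the largest magnitude difference, a standard-error-gated
    second test, and a significance-pattern fallback; step 3 assesses
    proportionality as linearity of the coefficient-versus-age relationship
    with a weighted lack-of-fit chi-square and diagnostic plots. Includes
    construction of 1:2 age- and CVD-matched case-control design sets, a
    synthetic exam-cohort generator with known age-dependent effect
    profiles, and Monte-Carlo operating-characteristic summaries, so the
    whole framework is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
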