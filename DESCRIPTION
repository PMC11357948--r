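Package: qepsgrowth
Title: QEPS Growth Curve Modelling of Pubertal Growth and Menarche Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the QEPS (Quadratic-Exponential-Pubertal-Stop) human growth
    model to individual longitudinal height series, extracts pubertal milestones
    (onset, midpuberty, peak height velocity, end of pubertal growth) and
    menarche-linked growth quantities (achieved pubertal fraction at menarche,
    height at menarche, postmenarcheal gain), imputes menarcheal age from
    questionnaire reports, and runs milestone-wise univariable and stepwise
    multivariable regression models with Bonferroni-Holm adjustment, standardized
    effects and partial R-squared. Includes a synthetic cohort generator
    calibrated to published cohort summaries of healthy term-born girls, so the
    whole pipeline is testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
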