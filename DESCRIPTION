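Package: metricsieve
Title: Data-Driven Selection and Validation of Digital Health Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A clinimetric selection and validation pipeline for sensor-based
    (digital health) metrics of upper-limb sensorimotor function. Implements
    mixed-effects confound normalization with Box-Cox transforms and
    parametric-bootstrap likelihood-ratio tests, model-quality gating,
    discriminant-validity (ROC/AUC), test-retest reliability (agreement ICC),
    measurement-error (smallest real difference) and learning-effect scoring,
    iterative partial-Spearman redundancy reduction, exploratory factor
    analysis with parallel analysis and KMO, disability-subgroup testing,
    kinematic and kinetic metric extraction (SPARC, dimensionless jerk, path
    length ratio, grip-force coordination) from pick-and-place recordings,
    and a synthetic-cohort generator with known ground truth for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
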