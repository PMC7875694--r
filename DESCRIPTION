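Package: impulsense
Title: Passive Smartphone Sensing Features and Impulsivity Prediction Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital phenotyping of impulsivity from everyday
    smartphone sensor streams. Reads and cleans durative event logs from
    three pervasive sensors (call logs, battery charging, screen unlocks),
    extracts fifteen behavioural features per participant-window (usage per
    hour, event frequency, duration mean and standard deviation, and
    hour-of-day occurrence entropy), and runs two prediction pipelines:
    a trait-level pipeline (feature/trait correlations, Lasso feature
    selection with an OLS refit, and leave-one-subject-out support vector
    regression) and a daily state-level pipeline (Gaussian generalized
    estimating equations with an exchangeable working correlation, plus
    median-split leave-one-subject-out logistic classification). A synthetic
    cohort generator with circadian event structure, planted trait effects,
    and agent-simulated mobile tasks (balloon risk task, go/no-go, adaptive
    delay discounting) makes every stage testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
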