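Package: goodspace
Title: Choice Models and Neuronal Encoding Analysis Under Variable Saccadic Action Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing value-based choices between juices offered at
    variable saccadic action costs, together with the spike-train encoding
    analyses used to ask whether such decisions are made in goods space.
    Provides a logistic choice model with cost, hysteresis and spatial-bias
    terms and its normalized behavioral indices; a Poisson spike-train
    simulator with ground-truth encoded variables for recovery testing; a
    three-way ANOVA screen for task-related responses; a multi-reference-frame
    variable catalog with stepwise and best-subset variable selection; ROC
    choice-probability analysis; and difference-of-R-squared tests of
    dimensional integration in value signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
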