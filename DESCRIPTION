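Package: pwmmrm
Title: Propensity-Weighted Mixed Models for Placebo-Controlled Trials
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of randomized placebo-controlled trials in major
    depressive disorder accounting for each subject's propensity to respond
    to placebo. Pre-randomization item-level rating-scale changes (HAMD-17
    by default) are used to train a multilayer-perceptron classifier of
    end-of-study placebo response; the inverse predicted probability enters
    a mixed model for repeated measures (REML, unstructured within-subject
    covariance) as an observation weight. Includes equipercentile linking
    utilities for response-threshold derivation, bootstrap ROC validation,
    a propensity sensitivity/bias analysis, and a synthetic-trial generator
    with latent placebo-response heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), nlme, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
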