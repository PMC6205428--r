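Package: facerevcorr
Title: Reverse-Correlation Modeling of Dynamic Facial Expressions of
    Intense Affect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of reverse-correlation experiments on
    dynamic facial expressions composed of facial action coding system
    (FACS) action units. Provides random stimulus generation with
    seven-parameter temporal activation profiles, synthetic observers for
    the categorization and word-matching validation tasks, per-observer
    expression-model fitting by binary (phi) correlation with temporal and
    intensity regressions, split-half Bernoulli naive Bayes classification,
    signal-detection (d-prime) analysis, mutual-information screening with
    max-statistic permutation nulls within and across cultures, and
    Hamming-distance comparison of fitted models against production-study
    action-unit patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
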