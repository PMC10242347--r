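Package: pairsurv
Title: Prognostic Analysis of Paired Tumor and Adjacent Normal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the prognostic value of tumor and
    tumor-adjacent normal tissue transcriptomes. Implements Cox
    proportional-hazards fitting by Newton-Raphson, Harrell's concordance
    index, Kaplan-Meier and log-rank statistics, distance-correlation
    gene screening against clinical Cox risk predictors, differential
    expression ratio features for paired designs, a Cox partial-likelihood
    neural network trained by gradient descent, and repeated hold-out
    evaluation protocols including feature-size sweeps, median-risk
    Kaplan-Meier stratification and cross-cohort prognostic similarity.
    A paired-cohort simulator with planted prognostic and differential
    expression structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
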