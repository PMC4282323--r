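Package: dtlshrink
Title: Shrinkage and Conditionally Unbiased Estimation for Two-Stage
    Drop-the-Loser Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Point estimation for the mean of the selected treatment in a
    two-stage drop-the-loser trial, where the best-performing of k
    experimental arms at stage 1 continues alone to stage 2 and the naive
    maximum likelihood estimate is inflated by selection.  Implements the
    precision-weighted MLE, the uniformly minimum variance conditionally
    unbiased estimator (UMVCUE), Carreras-Brannath stage-1 shrinkage, a
    direct empirical-Bayes plug-in based on a profile likelihood in the
    between-arm heterogeneity, Carter-Rolph standard-prior and
    proportional-prior shrinkage estimators built on meta-analytic
    machinery (generalised Q statistic, Paule-Mandel and
    DerSimonian-Laird tau-squared estimation), and a limited-translation
    variant constrained to one naive standard error of the MLE.  A
    vectorised Monte Carlo engine compares scaled bias and scaled
    root-mean-squared error of all estimators across trial scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
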