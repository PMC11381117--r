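Package: proxylearn
Title: Proxy-Process and Multi-Rate State-Space Models of Motor Learning
    Under Error Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial modelling of visuomotor skill acquisition with
    intermittent (catch-trial) feedback and error-augmentation training.
    Provides the family of autoregressive proxy-process error models (first-
    through eighth-order) and a dynamic-proxy multi-rate motor learning model
    with fast and slow states; a synthetic experiment generator reproducing
    the reaching-task design (triangular target layout, catch-trial schedules,
    cursor error augmentation, washout phases); multi-start bounded
    least-squares fitting with goodness-of-fit statistics; exhaustive
    cross-validation model selection with kernel-density-mode RMSE scoring and
    signed-rank comparison matrices; and weighted-bootstrap nonparametric
    inference (sign tests, rank-sum tests, median confidence intervals,
    steady-state error and washout time-constant analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
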