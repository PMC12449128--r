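Package: beliefvar
Title: Bayesian Observer Models and Across-Trial BOLD Signal Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking the reduction of belief uncertainty
    during sampling-based probability estimation to the compression of
    across-trial BOLD signal variability. Implements beta-binomial Bayesian
    observer models (prior-width and evidence-weight variants, truncated-normal
    and posterior-draw choice rules) and a Rescorla-Wagner comparison model,
    multi-start maximum-likelihood fitting with BIC model comparison and
    parameter/model recovery, behavioral accuracy metrics (estimation error,
    extreme-jar bias, winsorization), least-squares-single (LS-S) trial-wise
    GLM beta estimation with a canonical double-gamma HRF basis, across-trial
    SD-BOLD and change-in-SD-BOLD maps, condition-mean and parametric
    uncertainty GLMs, task and behavioral partial least squares with
    permutation and bootstrap inference, and a synthetic task/BOLD generator
    that provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
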