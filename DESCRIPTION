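Package: effortconn
Title: Effort-Based Decision Modelling and Brain-Connectivity Association
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking effort-based decision-making and apathy to
    fronto-motor brain connectivity. Implements a parametric choice-model
    family (linear, quadratic and exponential effort discounting with
    optional trial-wise time modulation) fitted by multi-start maximum
    likelihood with BIC model comparison; paired-pulse TMS motor-evoked-
    potential (MEP) trial cleaning and conditioned/test amplitude ratios;
    iteration-averaged streamline-count connectivity features for a fixed
    set of fronto-basal-ganglia-motor tract pairs; and a conservative
    two-step association procedure (cross-validated, iteration-averaged
    LASSO variable selection followed by confound-adjusted partial
    correlations, with Bayes-factor null evidence and Elastic Net and
    stepwise replications). A seeded synthetic-cohort generator emulates
    the full data structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
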