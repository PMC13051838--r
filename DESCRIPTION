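Package: oncoutreach
Title: Stochastic Counterfactual Simulation of Oncology Outreach Policies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and optimizing oncology outreach policies in
    hub-and-spoke cancer care networks. Samples incident cancer patients from a
    joint distribution over residence area, cancer type and stage; samples annual
    visit capacity across oncologist/site pairs; assigns patients to
    oncologist/site pairs with a capacity-constrained, first-come-first-served
    greedy algorithm that minimizes round-trip travel time; and compares paired
    counterfactual policy and control arms under common random numbers to
    estimate patient travel-time savings with percentile confidence intervals.
    Includes a grid search over the reallocation fraction, net-savings and
    follow-up extensions, a bootstrap supply/demand site-screening procedure,
    and a synthetic-catchment generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
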