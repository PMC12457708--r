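Package: matevar
Title: Variance Components and Cross-Context Correlations for Mate-Choice Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for isofemale-strain mate-choice
    experiments in Drosophila. Generates synthetic studies with known
    strain-level structure (censored mating-latency trials, four-male
    competition vials, competitive-fitness and egg-to-adult viability counts,
    nine-landmark wing configurations); binarizes noncompetitive latencies at a
    per-group quantile and converts competition vials to independent binary
    rows by repeated one-male-per-vial resampling; estimates male-strain
    standard deviations within, and correlations between, the four
    virgin/non-virgin by competition/no-competition contexts with a joint
    Bayesian hierarchical Bernoulli-logit model (Polya-Gamma Gibbs sampler,
    pooled posteriors, mode and highest-density credible intervals); confirms
    results with maximum-likelihood logistic mixed models, likelihood-ratio
    tests and strain-mean jackknifing; scores fitness and viability with a
    log-ratio statistic decomposed by Gaussian mixed models; and runs a
    generalized Procrustes / PCA / Mahalanobis-outlier morphometrics chain
    feeding strain-mean regressions of mating success on wing size, wing shape
    and sex-comb size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    generics,
    ggplot2,
    lme4,
    car,
    emmeans,
    readr,
    yaml,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
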