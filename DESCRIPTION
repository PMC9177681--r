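Package: tntmodel
Title: Trial-by-Trial Belief Models of Memory Intrusion Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models trial-by-trial beliefs about memory intrusions in
    think/no-think suppression experiments. Implements Rescorla-Wagner,
    Kalman-filter and two-level hierarchical Gaussian filter learning with
    state, item and precision-weighted combined belief sources, a
    beta-density response model with MAP estimation, a simulation-based
    validation suite (model falsification, trajectory, model and parameter
    recovery, group-difference power), random-effects Bayesian model
    selection with protected exceedance probabilities and Bayesian omnibus
    risk, Bayesian model averaging, construction of belief and
    prediction-error parametric modulators for connectivity modelling, and
    circular statistics for the balance between predictive and reactive
    memory control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
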