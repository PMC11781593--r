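Package: resetdyn
Title: Informed Stochastic Resetting for Langevin and Metadynamics Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to accelerate first-passage sampling in Langevin dynamics
    through stochastic resetting, including informed (state-conditional)
    resetting protocols layered on a batched underdamped BAOAB integrator,
    a minimal well-tempered Metadynamics engine with bias zeroing on reset,
    a trajectory-reweighting predictor that evaluates the mean first-passage
    time under any resetting rate and threshold from reset-free trajectories,
    extrapolation-based inference of the unbiased mean first-passage time
    from accelerated ensembles, and direct transit-time extraction from
    collective-variable time series. Ships analytic 2D model potentials
    (a modified Faradjian-Elber surface and a symmetric double well) and
    scripted experiments reproducing their resetting phenomenology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
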