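Package: mcmchfm
Title: Bayesian Parameter Inference for ODE Models with Hybrid Fitness Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Metropolis-Hastings parameter inference for kinetic (ODE) models
    where the likelihood is replaced by a product of hybrid fitness measures:
    qualitative fitnesses (0/1 indicators that a required bifurcation pattern,
    such as bistability or irreversibility, exists) and quantitative fitnesses
    (histogram or log-normal densities of trajectory observables such as
    execution time and endpoint concentration). Includes fixed-step
    Runge-Kutta simulation with optional additive Gaussian noise, steady-state
    and Jacobian-eigenvalue bifurcation analysis, synthetic fitness-histogram
    generation from noisy simulation ensembles, posterior summaries (marginal
    modes, 95 percent credible intervals, correlations, joint histograms,
    posterior-predictive observable histograms) and a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
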