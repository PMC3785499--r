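# Shared fixtures, built in code.

theta_answer <- c(k_d = 1.0, k_p = 1.0, K = 0.5)

toy <- toy_hill_model()
fixture <- bistable2d_model()

# closed form of the linear (feedback-disabled) toy model from y0 = 0
linear_solution <- function(t, k_s = 1, k_d = 1) (k_s / k_d) * (1 - exp(-k_d * t))

# independent steady-state oracle for 1-state models: dense sign-change scan
# refined by uniroot; deliberately shares no code with the package finder
bracket_oracle <- function(rhs, lo, hi, n = 10000) {
  g <- seq(lo, hi, length.out = n + 1)
  f <- rhs(g)  # rhs must be vectorized in y
  roots <- g[f == 0]
  for (i in which(f[-length(f)] * f[-1] < 0))
    roots <- c(roots, stats::uniroot(rhs, c(g[i], g[i + 1]), tol = 1e-13)$root)
  sort(roots)
}

# a short full-fitness toy chain shared across tests (built once per run)
.shared <- new.env()
shared_toy_fit <- function() {
  if (is.null(.shared$fit)) {
    hists <- generate_fitness_histograms(toy, n_replicates = 2000,
                                         noise_variance = 0.01, seed = 77)
    .shared$hists <- hists
    .shared$fit <- mcmc_hfm(
      toy, list(bistability_condition(), irreversibility_condition()),
      list(hists$Te, hists$Y100), prior = param_vector(theta_answer),
      config = mcmc_config(n_steps = 3e4, burn_in = 3e3, thin = 3, seed = 99),
      sim = list(input = 1.0))
  }
  .shared$fit
}
shared_toy_hists <- function() { shared_toy_fit(); .shared$hists }
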