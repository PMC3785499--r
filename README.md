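# mcmchfm — Bayesian parameter inference for ODE models with hybrid fitness measures

Kinetic models in systems biology typically carry more rate constants than
quantitative measurements, while the best-established experimental facts
are *qualitative*: a signalling switch is bistable, a committed state
persists when the stimulus is removed, a population-level response
histogram has a known shape. `mcmchfm` is for modellers who want to infer
kinetic parameters from exactly this mixture of evidence.

The package implements MCMC with **hybrid fitness measures** (MCMC-HFM): a
Metropolis–Hastings sampler whose target replaces the likelihood by a
product of

* **qualitative fitness measures** — indicators `I(C(θ))` that a required
  bifurcation pattern (steady-state counts and stabilities, optionally with
  output thresholds) exists, evaluated by Newton–Raphson steady-state
  location and Jacobian-eigenvalue stability analysis; and
* **quantitative fitness measures** — for a scalar observable `z(θ)` from
  one deterministic simulation, either the frequency of the histogram bin
  `z` falls in, or a log-normal density with moments matched to reported
  mean ± SD,

over a log-uniform box prior:

    π(θ | data) ∝ f_quant(z_n(θ)) ⋯ f_quant(z_{m+1}(θ)) · I(C_m(θ)) ⋯ I(C_1(θ)) · π(θ).

Proposals perturb one randomly chosen parameter on the log10 scale
(uniform half-width σ_q, or a normal variant); with the flat prior the
acceptance probability is `min(1, w*/w)` on the fitness product, so every
retained sample satisfies every qualitative condition by construction.

The package ships a one-variable Hill-feedback toy model
(`d[Y]/dt = k_s − k_d[Y] + k_p[Y]⁵/(K⁵+[Y]⁵)`), a two-variable bistable
fixture for multi-state stability analysis, a plug-in contract for user
models, fixed-step RK4 simulation with optional additive Gaussian noise, a
synthetic-data generator that builds fitness histograms from noisy
simulation ensembles, posterior summaries (marginal modes, 95% credible
intervals and their log10 widths, correlations, joint histograms,
posterior-predictive observable histograms) and a small CLI.

## Worked example: recovering known parameters

Generate population-style histograms from 10000 noisy simulations at the
"true" parameters, then infer those parameters back from bistability (B),
irreversibility (I) and the two histograms:

```r
library(mcmchfm)
model <- toy_hill_model()

find_steady_states(model, c(k_d = 1, k_p = 1, K = 0.5), input = 0.2)
#> 3 steady state(s) at input = 0.2 (model 'toy')
#>           Y stability max_re_eigenvalue
#> 1 0.2142359    stable        -0.6724823
#> 2 0.3575644  unstable         0.8561393
#> 3 1.1869069    stable        -0.9455657

hists <- generate_fitness_histograms(model, n_replicates = 10000,
                                     noise_variance = 0.01, seed = 1)
hists$Te
#> Histogram fitness on execution time of Y (90% of max): 50 bins over [2.18, 20.35], total frequency 10000

fit <- mcmc_hfm(model,
                conditions = list(bistability_condition(),
                                  irreversibility_condition()),
                fitness = list(hists$Te, hists$Y100),
                prior = param_vector(c(k_d = 1, k_p = 1, K = 0.5)),
                config = mcmc_config(n_steps = 1.1e5, burn_in = 1e4,
                                     thin = 3, seed = 1),
                sim = list(input = 1.0))
summary(fit)
#> Posterior summary (33333 samples, 95% credible intervals):
#>       mode mode_log10 ci_lower ci_upper log10_width
#> k_d 1.0471      0.020   0.8551   1.1054      0.1115
#> k_p 0.9550     -0.020   0.7312   1.2661      0.2384
#> K   0.5236     -0.281   0.4522   0.6089      0.1293
#> per-parameter acceptance rates: k_d = 0.0342, k_p = 0.0732, K = 0.0873
```

The three steady states at `k_s = 0.2` (two stable flanking one unstable)
are the saddle-node signature behind condition B. The marginal modes land
on the bins containing the generating values (1.0, 1.0, 0.5): mode bins are
0.04 log10 units wide, so `mode_log10` of ±0.02 is the closest attainable
bin centre to a truth sitting on a bin edge. `log10_width` is the common
log of the 95% interval's upper/lower ratio — about 0.11–0.24 decades here,
versus 2.0 for a posterior as wide as the prior box. Dropping the
quantitative histograms (`fitness = list()`) widens these to ≈1.6–1.8,
which is the package's reproduction of the central claim: each added
fitness measure narrows the credible parameter range.

`correlation_matrix(fit)` exposes the compensating pair behind the
remaining uncertainty (r ≈ 0.89 between log10 k_d and log10 k_p here), and
`predict(fit, obs_execution_time("Y"), breaks = hists$Te$bin_edges)` gives
the posterior-predictive execution-time histogram for comparison with the
data.

A command-line driver wraps the same functions
(`inst/scripts/hfm <simulate|bifurcate|make-fitness|sample|analyze|recover>
--config run.json`), driven by a single validated JSON config; see
`?validate_config`.

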