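---
title: "Parameter inference with hybrid fitness measures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter inference with hybrid fitness measures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmchfm)
```

## The inference problem

Kinetic models of signalling networks come with many unknown rate constants
and few quantitative measurements. What experiments often *do* establish is
qualitative: a pathway is switch-like (bistable), a committed state persists
after the stimulus is removed (irreversible), a response histogram over a
cell population has a particular location and spread. `mcmchfm` implements
Metropolis–Hastings sampling where the likelihood is replaced by a product
of **hybrid fitness measures** over a log-uniform box prior:

* **Qualitative fitness** `I(C(θ))`: a 0/1 indicator that a declared
  bifurcation pattern exists at parameter vector θ — for example, "exactly
  two stable and one unstable steady state at input 0.2". These are
  evaluated by steady-state location and Jacobian-eigenvalue stability
  analysis, never by simulating trajectories.
* **Quantitative fitness** `f_quant(z(θ))`: a non-negative score of a
  scalar observable `z(θ)` extracted from one deterministic simulation —
  either the *frequency of the histogram bin* the simulated value falls in
  (when a population histogram is available) or a *log-normal density*
  parameterized by a reported mean and SD (when only summary moments are
  known).

The sampled target is `∏ f_quant · ∏ I(C) · π(θ)` with `π` flat on the
log10 scale inside the box. Because the single-coordinate proposal is
symmetric and the prior flat, the acceptance probability reduces to
`min(1, w*/w)` on the fitness product; a chain state never has zero weight,
so every retained sample satisfies every qualitative condition by
construction. Detailed balance holds for the same reason it does for
ordinary Metropolis sampling — the indicator factors simply zero some
acceptance ratios — and the package verifies the stationary law empirically
against a brute-force normalized target on a discretized one-parameter
problem.

## The toy model and its study conditions

The built-in test bed is a one-variable Hill-feedback model,

$$\frac{d[Y]}{dt} = k_s - k_d\,[Y] + k_p\frac{[Y]^n}{K^n + [Y]^n},
\qquad n = 5,$$

with synthesis input $k_s$, degradation rate $k_d$, feedback strength $k_p$
and feedback threshold $K$. At the reference values
$(k_d, k_p, K) = (1.0, 1.0, 0.5)$ the system is bistable at intermediate
input and keeps its high branch at $k_s = 0$. Two qualitative conditions
encode this:

* **B** (bistability): 2 stable + 1 unstable state at $k_s = 0.2$; exactly
  one stable state at $k_s = 0.3$ and at $k_s = 1.0$;
* **I** (irreversibility): B plus 2 stable + 1 unstable at $k_s = 0$.

Counts are required to match *exactly* (a "at least" reading would accept
qualitatively different diagrams), and any marginal eigenvalue
(|Re λ| < 1e−8) conservatively fails the clause: conditions assert robust
patterns, not knife-edge ones.

Quantitative fitness histograms are generated the way a population
experiment would produce them: 10000 simulations at the reference
parameters with additive Gaussian noise, observing the **execution time**
`T_e` (first time Y reaches 90% of its trajectory maximum) and the
**endpoint concentration** at time 100, each histogrammed into 50
equal-width bins over the replicate range. The study's default noise
variance is 1; the sharper variance-0.01 variant is what the package's
acceptance analyses use, because sharp histograms make mode recovery
unambiguous at reduced chain length.

For signalling-style applications the package also provides the
**switching time** (2.5% → 97.5% crossing gap) and log-normal fitness
specifications from reported moments — e.g. a switching time of 23 ± 10
minutes and an execution time of 15 ± 3 minutes — via
`lognormal_from_moments()`, which inverts
$\sigma^2 = \log(1 + sd^2/mean^2)$, $\mu = \log(mean) - \sigma^2/2$.
A two-variable bistable fixture model (`bistable2d_model()`) exercises the
multi-state machinery: multi-start Newton root finding, complex Jacobian
spectra, and output thresholds that select the lower or higher stable
branch ("the inactive branch stays below 1.0 nM"-style clauses).

## Numerical design choices

**Integration.** Classical fixed-step RK4 with `dt = 0.01` to `t_end = 100`
(10000 steps) — the regime where the observables live; the convergence test
fits an empirical order ≥ 3.5 against the linear model's closed form.
Adaptive or stiff integrators are out of scope.

**Noise injection.** "Additive Gaussian noise in the model" is realized as
a post-step diffusion increment $\epsilon\sqrt{dt}$, $\epsilon \sim
N(0, \sigma^2)$, so that the stated per-model variance has a
time-step-robust meaning (an Euler–Maruyama reading); states are clamped at
zero because concentrations cannot be negative. Zero variance reproduces
the deterministic integrator bitwise. Whether the original study clamped,
or how its noise interacted with dt, is not stated anywhere we could
verify; the rule is recorded in every trajectory and histogram sidecar.

**Steady states.** For one-state models the primary finder brackets sign
changes on a dense regular grid, refines by bisection and polishes by
Newton — exhaustive up to grid resolution. The bracket is *parameter
adaptive*: every root of the toy rhs satisfies
$k_d y = k_s + k_p h$ with $h \in [0,1]$, so $[0, (k_s+k_p)/k_d + 1]$
provably contains all of them (a fixed interval like [0, 5] silently loses
the upper branch in the large-$k_p$/small-$k_d$ corner of the prior box and
breaks the odd-root-count parity that a generic saddle-node structure
implies). For two or more states a multi-start Newton–Raphson iteration
runs from a regular grid (default 50 starts per dimension); converged
iterates outside the physical search box — Newton happily finds
negative-concentration roots of the same algebraic system — are discarded.
Roots are verified (`max|rhs| ≤ 1e−10`), deduplicated within `1e−6`, and
classified by the sign of the largest real eigenvalue part with a `1e−8`
marginal band. Root finding inside the sampler uses a 4000-point grid
(`mcmc_config(steady_grid=)`); standalone analysis defaults to 10⁴. The
test suite cross-checks the finder against an independent
`uniroot`-refined scan over 200 random prior draws at all four condition
inputs.

**Observables.** Maxima are taken over the trajectory grid, and crossing
times are first grid times meeting the threshold, with no interpolation:
at `dt = 0.01` interpolation error is negligible and the discrete rule is
exactly reproducible. Constant (including all-zero) trajectories report
time 0. Histogram lookups use half-open bins `[e_i, e_{i+1})` with the last
bin closed; raw frequencies are used rather than normalized densities,
since only fitness *ratios* enter the acceptance probability and raw counts
keep provenance with the generator.

**Sampling.** One coordinate of log10 θ is chosen uniformly per step and
shifted by $\sigma_q(2r-1)$ (uniform kind, default, $\sigma_q = 0.5$) or
$\sigma_q \varepsilon$ with $\varepsilon \sim N(0,1)$ (normal kind).
Out-of-box candidates are rejected rather than reflected — the simplest
correct treatment of a flat box prior. Qualitative conditions are evaluated
before any dynamics so failing candidates never cost an integration; the
evaluation order cannot change the target. Chains start at the model's
reference vector by default (the acceptance ratio is undefined from a
zero-weight state), falling back to rejection sampling from the prior with
a 10⁵-draw budget. Rejected steps repeat the current state in the thinned
record; the current weight is cached and invalidated only on acceptance —
the suite recomputes retained weights from scratch and requires exact
equality. All randomness flows through R's RNG (also inside the compiled
loop), so a single seed reproduces generator and chain bit-for-bit.

**Posterior summaries.** Marginals are histogrammed in 50 bins over the
prior box (two decades → 0.04 log10 units per bin); the mode is the centre
of the maximal bin, leftmost on ties. The 95% credible interval uses
nearest-rank 2.5%/97.5% quantiles, exponentiated, and credibility is
reported as log10(upper/lower) — 2.0 means "the prior box", 0 means a point
mass.

## Problem sizes used by the tests and acceptance analyses

The study conditions themselves (histograms from 10000 noisy replicates;
$\sigma_q = 0.5$; thinning by 3) are kept; chain lengths are scaled down
from the original 3×10⁶ post-burn-in steps, which recovery does not need:

* recovery runs (test and reproduction script) use 6×10⁵ post-burn-in
  steps, 2×10⁵ retained samples. One caveat worth knowing: the generating
  values sit exactly on marginal-bin edges, and the realized generator
  histograms shift the posterior peak by up to about half a bin, so the
  reported mode bin for $k_d$ and $k_p$ can legitimately land one bin
  (0.04 log10 units, ~10% linear) to the left of the generating value for
  some generator seeds — a property of the scaled-down, sharp-histogram
  pipeline itself, not of the chain length;
* credible-interval-ordering comparisons use 1.5×10⁵ post-burn-in steps
  per fitness subset on three seeds — interval *widths* are far less
  Monte-Carlo sensitive than mode bins;
* sampler-calibration chains use 10⁶ steps on the dynamics-free tabulated
  target (total-variation check) and 10⁵ retained samples for the
  flat-target uniformity check.

## What the synthetic generator does and does not emulate

The generator reproduces the *procedure* that made the study's data — noise
inside the dynamics, observables extracted per replicate, equal-width
binning over the replicate range — so recovery tests close the loop
end-to-end: parameters → noisy data → histograms → posterior → parameters.
It does not emulate features of real population data: extrinsic
cell-to-cell parameter variability, measurement error on the observable
itself, finite detection thresholds, or asynchronous time origins. Passing
recovery tests therefore demonstrates the *inference machinery* is sound,
not that the noise model matches any particular experiment. The
max-over-grid definition of `T_e` also makes noisy replicates upward-biased
relative to the deterministic value (an excursion can raise the maximum),
which is visible as a right tail in the generated histograms; the same
definition is applied consistently on both the data and inference sides.

## Known limitations

* Exact-count conditions plus a finite bracketing grid mean parameter
  vectors within ~grid-spacing of a saddle-node bifurcation can be
  misclassified; the marginal band only catches exact degeneracy.
* Histogram fitness gives zero weight outside the observed sample range, so
  the posterior support is clipped to the data histogram's span; this is
  inherent to the frequency-lookup fitness, not a sampler artifact.
* The single-coordinate proposal mixes slowly across strongly correlated
  ridges (visible in the B-I-only posterior, where $k_d$ and $K$ co-vary);
  no adaptive or population MCMC is provided.
* User-registered models run through the R engine, roughly two orders of
  magnitude slower than the compiled path for the built-in models.
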