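#' Generate quantitative fitness histograms from noisy simulation ensembles
#'
#' Emulates population-level experimental histograms: the model is simulated
#' `n_replicates` times at a known "true" parameter vector with additive
#' Gaussian noise, the requested observables are extracted from every
#' replicate, and each observable is histogrammed into `n_bins` equal-width
#' bins spanning the replicate min/max.  The defaults are the toy-model
#' study conditions: 10000 replicates at input `k_s = 1.0` with noise
#' variance 1, observing the execution time of Y and the concentration of Y
#' at time 100.
#'
#' Replicates whose integration fails or whose observable is undefined are
#' dropped; more than 1% drops is an error.
#'
#' @param model an `hfm_model`.
#' @param true_params generating parameter vector (`hfm_params` or named
#'   linear vector); defaults to the model's reference values.
#' @param input input level during generation.
#' @param n_replicates number of noisy simulations.
#' @param noise_variance variance of the additive Gaussian noise.
#' @param observables named list of `hfm_observable` descriptors.
#' @param n_bins equal-width bins per histogram.
#' @param t_end,dt integration settings.
#' @param seed optional RNG seed.
#' @return named list of `hfm_fitness` histograms; each carries a
#'   `"generator"` attribute recording the settings and drop count.
#' @examples
#' \donttest{
#' h <- generate_fitness_histograms(toy_hill_model(), n_replicates = 200,
#'                                  noise_variance = 0.01, seed = 1)
#' h$Te
#' }
#' @export
generate_fitness_histograms <- function(model, true_params = NULL,
                                        input = NULL, n_replicates = 10000,
                                        noise_variance = 1,
                                        observables = NULL, n_bins = 50,
                                        t_end = 100, dt = 0.01, seed = NULL) {
  stopifnot(inherits(model, "hfm_model"), n_replicates >= 1)
  if (is.null(true_params)) true_params <- model$reference
  if (is.null(input)) input <- model$default_input
  if (is.null(observables))
    observables <- list(Te = obs_execution_time(model$state_names[1]),
                        Y100 = obs_endpoint(model$state_names[1], t_end))
  if (!length(observables) || is.null(names(observables)))
    stop("observables must be a non-empty named list")
  if (!is.null(seed)) set.seed(seed)
  pars <- .model_pars(model, true_params)
  nsteps <- round(t_end / dt)
  code <- vapply(observables, `[[`, integer(1), "code")
  if (any(code > 2L)) stop("generator observables must be trajectory-valued")
  st <- vapply(observables, function(o)
    match(o$state, model$state_names) - 1L, integer(1))
  p1 <- vapply(observables, `[[`, numeric(1), "p1")
  p2 <- vapply(observables, `[[`, numeric(1), "p2")
  vals <- if (!is.na(model$cpp_id)) {
    cpp_noisy_ensemble(model$cpp_id, unname(pars), input, rep(0, model$d),
                       dt, nsteps, sqrt(noise_variance), n_replicates,
                       code, st, p1, p2)
  } else {
    t(vapply(seq_len(n_replicates), function(i) {
      tr <- simulate_noisy(model, pars, input, t_end = t_end, dt = dt,
                           noise_variance = noise_variance)
      vapply(observables, function(o)
        switch(o$kind,
               execution_time = execution_time(tr, o$state, o$p1),
               switching_time = switching_time(tr, o$state, o$p1, o$p2),
               endpoint = endpoint_value(tr, o$state, o$p1)),
        numeric(1))
    }, numeric(length(observables))))
  }
  out <- list()
  for (k in seq_along(observables)) {
    v <- vals[, k]
    dropped <- sum(!is.finite(v))
    if (dropped > 0.01 * n_replicates)
      stop("more than 1% of replicates failed for observable ",
           names(observables)[k], " (", dropped, " of ", n_replicates, ")")
    f <- .histogram_from_values(observables[[k]], v[is.finite(v)], n_bins)
    attr(f, "generator") <- list(model = model$key, input = input,
                                 n_replicates = n_replicates,
                                 noise_variance = noise_variance,
                                 n_bins = n_bins, t_end = t_end, dt = dt,
                                 seed = seed, dropped = dropped)
    out[[names(observables)[k]]] <- f
  }
  out
}

#' End-to-end parameter recovery experiment on the toy model
#'
#' Runs the full pipeline the inference test is built on: generate fitness
#' histograms from noisy simulations at the true parameters, sample with
#' MCMC-HFM under a chosen subset of fitness measures, and summarize the
#' marginals.  The report records, per parameter, the marginal mode, 95%
#' credible interval and the absolute log10 error of the mode against the
#' generating value.
#'
#' @param fitness_subset character subset of `c("B", "I", "Te", "Y100")`:
#'   bistability, irreversibility, execution-time histogram, endpoint
#'   histogram.
#' @param noise_variance generator noise variance (default 0.01, the
#'   sharp-histogram variant).
#' @param config an [mcmc_config()]; the default is a tenfold scaled-down
#'   chain (3.3e5 steps, 3e4 burn-in, thin 3).
#' @param n_replicates generator ensemble size.
#' @param n_bins marginal histogram bins for the report.
#' @param seed master seed for generation and sampling.
#' @return list with `report` (data frame), `fit` (the `hfm_fit`) and
#'   `histograms` (the generated fitness measures).
#' @export
recovery_experiment <- function(fitness_subset = c("B", "I", "Te", "Y100"),
                                noise_variance = 0.01,
                                config = mcmc_config(n_steps = 3.3e5,
                                                     burn_in = 3e4, thin = 3),
                                n_replicates = 10000, n_bins = 50,
                                seed = NULL) {
  stopifnot(length(fitness_subset) >= 1,
            all(fitness_subset %in% c("B", "I", "Te", "Y100")))
  if (!is.null(seed)) set.seed(seed)
  model <- toy_hill_model()
  truth <- model$reference
  hists <- generate_fitness_histograms(model, truth, input = 1.0,
                                       n_replicates = n_replicates,
                                       noise_variance = noise_variance)
  conditions <- c(if ("B" %in% fitness_subset) list(bistability_condition()),
                  if ("I" %in% fitness_subset) list(irreversibility_condition()))
  fitness <- c(if ("Te" %in% fitness_subset) list(hists$Te),
               if ("Y100" %in% fitness_subset) list(hists$Y100))
  prior <- param_vector(truth)   # log-uniform box: one decade either side
  fit <- mcmc_hfm(model, conditions, fitness, prior, config,
                  sim = list(input = 1.0))
  s <- summary(fit, n_bins = n_bins)
  report <- cbind(s$table,
                  truth_log10 = log10(truth)[s$table$parameter],
                  abs_err_log10 = abs(s$table$mode_log10 -
                                        log10(truth)[s$table$parameter]))
  list(report = report, fit = fit, histograms = hists,
       fitness_subset = fitness_subset, noise_variance = noise_variance)
}
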