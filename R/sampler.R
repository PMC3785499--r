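#' MCMC configuration
#'
#' Defaults follow the toy-model study conditions: 3.3 million Monte Carlo
#' steps with the first 0.3 million discarded as burn-in, every 3rd step
#' recorded (one million retained samples), and a symmetric uniform
#' single-coordinate proposal of half-width `sigma_q = 0.5` on the log10
#' scale.  Scaled-down analyses pass smaller step counts explicitly.
#'
#' @param n_steps total Monte Carlo steps.
#' @param burn_in discarded prefix (must be smaller than `n_steps`).
#' @param thin record every `thin`-th post-burn-in step.
#' @param sigma_q proposal half-width (uniform) or SD (normal) on log10 scale.
#' @param proposal `"uniform"`: shift one coordinate by `sigma_q*(2r - 1)`
#'   with \eqn{r \sim U(0,1)}; `"normal"`: shift by `sigma_q * N(0,1)`.  Both are
#'   symmetric.
#' @param seed optional RNG seed applied at chain start.
#' @param init `"reference"` (start at the prior's reference values),
#'   `"random"` (rejection-sample a positive-weight start from the prior
#'   box), or a named numeric log10 vector.
#' @param steady_grid grid resolution used by the 1-D steady-state finder
#'   inside qualitative condition checks.
#' @return list of class `hfm_mcmc_config`.
#' @export
mcmc_config <- function(n_steps = 3.3e6, burn_in = 0.3e6, thin = 3,
                        sigma_q = 0.5, proposal = c("uniform", "normal"),
                        seed = NULL, init = "reference", steady_grid = 4000) {
  proposal <- match.arg(proposal)
  stopifnot(n_steps >= 1, burn_in >= 0, burn_in < n_steps, thin >= 1,
            sigma_q > 0)
  structure(list(n_steps = n_steps, burn_in = burn_in, thin = as.integer(thin),
                 sigma_q = sigma_q, proposal = proposal, seed = seed,
                 init = init, steady_grid = as.integer(steady_grid)),
            class = "hfm_mcmc_config")
}

.sim_spec <- function(model, sim) {
  out <- list(input = if (is.null(model)) 0 else model$default_input,
              t_end = 100, dt = 0.01, y0 = NULL)
  for (nm in names(sim)) out[[nm]] <- sim[[nm]]
  if (is.null(out$y0) && !is.null(model)) out$y0 <- rep(0, model$d)
  out$nsteps <- round(out$t_end / out$dt)
  out
}

#' Single-coordinate symmetric proposal
#'
#' Picks one parameter uniformly at random and perturbs it on the log10
#' scale: by `sigma_q * (2r - 1)` with \eqn{r \sim U(0,1)} for the uniform kind, or
#' by `sigma_q * N(0,1)` for the normal kind.
#'
#' @param current an `hfm_params` (its log10 values are perturbed).
#' @param sigma_q proposal half-width / SD on the log10 scale.
#' @param proposal `"uniform"` or `"normal"`.
#' @return list with `params` (the candidate `hfm_params`) and `index` (the
#'   perturbed coordinate).
#' @export
propose <- function(current, sigma_q = 0.5, proposal = c("uniform", "normal")) {
  stopifnot(inherits(current, "hfm_params"))
  proposal <- match.arg(proposal)
  j <- sample.int(length(current$log10), 1)
  delta <- if (proposal == "uniform") sigma_q * (2 * stats::runif(1) - 1)
           else sigma_q * stats::rnorm(1)
  v <- current$log10
  v[j] <- v[j] + delta
  list(params = set_log10_values(current, v), index = j)
}

#' Metropolis acceptance probability for hybrid-fitness targets
#'
#' With a symmetric proposal and a flat (log-uniform) prior inside the box,
#' the acceptance probability reduces to
#' `min(1, weight_candidate / weight_current)`.  A candidate failing any
#' qualitative condition has weight 0 and is never accepted; the chain must
#' never occupy a zero-weight state, so `weight_current = 0` is an error.
#'
#' @param weight_candidate,weight_current non-negative target weights.
#' @return acceptance probability in `[0, 1]`.
#' @export
acceptance_probability <- function(weight_candidate, weight_current) {
  if (!(weight_current > 0))
    stop("chain invariant violated: current state has zero target weight")
  min(1, weight_candidate / weight_current)
}

#' Hybrid-fitness target weight of a parameter vector
#'
#' Evaluates the (unnormalized) posterior weight: 0 outside the prior box;
#' otherwise the qualitative indicators are checked first by bifurcation
#' analysis (any failure short-circuits to 0 without running dynamics), then
#' a single deterministic simulation provides all trajectory observables and
#' the weight is the product of the quantitative fitness values.
#'
#' @param params an `hfm_params` (values = the point to evaluate, bounds =
#'   the prior box).
#' @param model an `hfm_model`, or `NULL` when no fitness needs dynamics or
#'   bifurcation analysis.
#' @param conditions list of `hfm_condition` qualitative fitness measures.
#' @param fitness list of `hfm_fitness` quantitative fitness measures.
#' @param sim named list overriding simulation settings (`input`, `t_end`,
#'   `dt`, `y0`).
#' @param steady_grid 1-D steady-state grid resolution for condition checks.
#' @return list with `weight`, `qualitative` (named 0/1 per condition),
#'   `quantitative` (named fitness factors) and `observables`.
#' @examples
#' theta <- param_vector(c(k_d = 1, k_p = 1, K = 0.5))
#' target_weight(theta, toy_hill_model(),
#'               conditions = list(bistability_condition()))$weight
#' @export
target_weight <- function(params, model = NULL, conditions = list(),
                          fitness = list(), sim = list(),
                          steady_grid = 4000) {
  stopifnot(inherits(params, "hfm_params"))
  ss <- .sim_spec(model, sim)
  qual <- stats::setNames(rep(NA_integer_, length(conditions)),
                          vapply(conditions, `[[`, character(1), "name"))
  quant <- stats::setNames(rep(NA_real_, length(fitness)),
                           vapply(fitness, function(f) obs_label(f$observable),
                                  character(1)))
  obs <- quant
  out <- list(weight = 0, qualitative = qual, quantitative = quant,
              observables = obs)
  if (!all(in_prior_box(params))) return(out)

  P <- .encode_problem(model, conditions, fitness, params, ss, steady_grid)
  compiled <- !is.null(P)
  for (i in seq_along(conditions)) {
    out$qualitative[i] <- evaluate_condition(conditions[[i]], model, params,
                                             n_grid = steady_grid)
    if (out$qualitative[i] == 0L) return(out)
  }
  traj <- NULL
  needs_dyn <- any(vapply(fitness, function(f) f$observable$code <= 2L,
                          logical(1)))
  if (needs_dyn) {
    traj <- tryCatch(
      integrate_rk4(model, params, ss$input, ss$y0, ss$t_end, ss$dt),
      error = function(e) {
        warning("integration failed: ", conditionMessage(e)); NULL
      })
    if (is.null(traj)) return(out)
  }
  for (i in seq_along(fitness)) {
    f <- fitness[[i]]
    o <- f$observable
    z <- switch(o$kind,
                parameter = if (o$code == 3L) params$log10[[o$param]]
                            else 10^params$log10[[o$param]],
                execution_time = execution_time(traj, o$state, o$p1),
                switching_time = switching_time(traj, o$state, o$p1, o$p2),
                endpoint = endpoint_value(traj, o$state, o$p1))
    out$observables[i] <- z
    out$quantitative[i] <- eval_fitness(f, z)
  }
  # the compiled kernel is the canonical weight where available, so that
  # cached chain weights reproduce exactly
  out$weight <- if (compiled) cpp_target_weight(P, unname(params$log10))
                else prod(out$quantitative, 1)
  out
}

# Encode a problem for the compiled kernel, or NULL when unsupported
# (user-registered models, multi-state models, threshold clauses).
.encode_problem <- function(model, conditions, fitness, prior, ss,
                            steady_grid) {
  model_id <- if (is.null(model)) 0L else model$cpp_id
  if (is.na(model_id) || model_id == 2L) return(NULL)
  cl <- matrix(numeric(0), 0, 3)
  for (cond in conditions) {
    for (clz in cond$clauses) {
      if (length(clz$thresholds)) return(NULL)
      cl <- rbind(cl, c(clz$input, clz$n_stable, clz$n_unstable))
    }
  }
  if (nrow(cl) && model_id == 0L) return(NULL)
  cl <- unique(cl)
  fit <- lapply(fitness, function(f) {
    o <- f$observable
    st <- if (!is.na(o$state) && !is.null(model))
      match(o$state, model$state_names) - 1L else 0L
    pj <- if (!is.na(o$param)) match(o$param, prior$names) - 1L else 0L
    if (is.na(st) || is.na(pj)) stop("fitness references unknown state/parameter")
    base <- list(type = if (f$type == "histogram") 0L else 1L,
                 obs_code = o$code, state = st, par_idx = pj,
                 p1 = o$p1, p2 = o$p2)
    if (f$type == "histogram")
      c(base, list(edges = f$bin_edges, freq = f$frequencies))
    else c(base, list(mu = f$mu, sigma = f$sigma))
  })
  needs_dyn <- any(vapply(fitness, function(f) f$observable$code <= 2L,
                          logical(1)))
  if (needs_dyn && model_id == 0L) return(NULL)
  list(model = model_id, lower = unname(prior$lower),
       upper = unname(prior$upper), grid_n = steady_grid,
       clause_input = cl[, 1], clause_ns = as.integer(cl[, 2]),
       clause_nu = as.integer(cl[, 3]),
       sim_input = ss$input, sim_dt = ss$dt,
       sim_nsteps = as.integer(ss$nsteps),
       sim_y0 = if (is.null(ss$y0)) 0 else as.numeric(ss$y0),
       fitness = fit)
}

#' Run the hybrid-fitness Metropolis-Hastings sampler
#'
#' Samples kinetic parameters from the posterior proportional to
#' `prod(f_quant) * prod(I(C)) * prior`, with a log-uniform box prior and a
#' symmetric single-coordinate proposal.  Each step proposes a perturbation
#' of one randomly chosen parameter on the log10 scale; candidates outside
#' the prior box or failing any qualitative condition are rejected, others
#' are accepted with probability `min(1, w*/w)`.  Rejected steps repeat the
#' current state in the recorded (burn-in-discarded, thinned) trace.
#'
#' For the built-in toy model (and for problems with only parameter
#' observables) the whole loop runs in compiled code; user-registered models
#' run through an R loop with identical semantics.  All randomness draws
#' from R's RNG, so `config$seed` (or a prior `set.seed()`) makes runs
#' reproducible.
#'
#' @param model an `hfm_model`, or `NULL` for targets without dynamics.
#' @param conditions list of `hfm_condition` (qualitative fitness measures).
#' @param fitness list of `hfm_fitness` (quantitative fitness measures).
#' @param prior an `hfm_params`: bounds define the log-uniform prior box,
#'   values the reference/initial point.
#' @param config an [mcmc_config()].
#' @param sim named list overriding simulation settings (`input`, `t_end`,
#'   `dt`, `y0`) for trajectory observables.
#' @param engine `"auto"` (compiled when possible), `"compiled"` or `"r"`.
#' @return an object of class `hfm_fit` with the retained log10 samples,
#'   per-sample weights, per-parameter acceptance counts and the full
#'   configuration; see [summary.hfm_fit()], [coef.hfm_fit()],
#'   [plot.hfm_fit()].
#' @examples
#' \donttest{
#' prior <- param_vector(c(k_d = 1, k_p = 1, K = 0.5))
#' fit <- mcmc_hfm(toy_hill_model(),
#'                 conditions = list(bistability_condition()),
#'                 prior = prior,
#'                 config = mcmc_config(n_steps = 2e4, burn_in = 2e3,
#'                                      thin = 2, seed = 1))
#' summary(fit)
#' }
#' @export
mcmc_hfm <- function(model = NULL, conditions = list(), fitness = list(),
                     prior, config = mcmc_config(), sim = list(),
                     engine = c("auto", "compiled", "r")) {
  stopifnot(inherits(prior, "hfm_params"), inherits(config, "hfm_mcmc_config"))
  engine <- match.arg(engine)
  if (!is.null(config$seed)) set.seed(config$seed)
  ss <- .sim_spec(model, sim)
  P <- .encode_problem(model, conditions, fitness, prior, ss,
                       config$steady_grid)
  if (engine == "compiled" && is.null(P))
    stop("problem not supported by the compiled engine; use engine = \"r\"")
  use_cpp <- engine != "r" && !is.null(P)

  wfun <- function(v) target_weight(set_log10_values(prior, v), model,
                                    conditions, fitness, sim,
                                    config$steady_grid)$weight
  theta0 <- .initial_state(prior, config, wfun)

  t0 <- proc.time()[["elapsed"]]
  if (use_cpp) {
    res <- cpp_mcmc(P, unname(theta0), config$n_steps, config$burn_in,
                    config$thin, config$sigma_q,
                    if (config$proposal == "uniform") 0L else 1L)
  } else {
    res <- .mcmc_r(wfun, theta0, prior, config)
  }
  colnames(res$samples) <- prior$names
  structure(list(samples = res$samples, weights = res$weights,
                 accept = stats::setNames(res$accept, prior$names),
                 propose = stats::setNames(res$propose, prior$names),
                 model = model, conditions = conditions, fitness = fitness,
                 prior = prior, config = config, sim = ss,
                 engine = if (use_cpp) "compiled" else "r",
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "hfm_fit")
}

.initial_state <- function(prior, config, wfun, budget = 1e5) {
  if (is.numeric(config$init)) {
    v <- config$init[prior$names]
    if (any(is.na(v))) stop("init vector must name every parameter")
    if (wfun(v) > 0) return(stats::setNames(v, prior$names))
    stop("supplied initial state has zero target weight")
  }
  if (identical(config$init, "reference")) {
    v <- prior$log10
    if (wfun(v) > 0) return(v)
    # fall through to rejection sampling when the reference has zero weight
  }
  d <- length(prior$log10)
  for (i in seq_len(budget)) {
    v <- prior$lower + stats::runif(d) * (prior$upper - prior$lower)
    if (wfun(v) > 0) return(stats::setNames(v, prior$names))
  }
  stop("could not find a positive-weight initial state in ", budget, " draws")
}

# plain-R Metropolis loop (user models, threshold conditions)
.mcmc_r <- function(wfun, theta0, prior, config) {
  d <- length(theta0)
  cur <- as.numeric(theta0)
  wcur <- wfun(cur)
  if (!(wcur > 0)) stop("initial state has zero target weight")
  nrec <- floor((config$n_steps - config$burn_in) / config$thin)
  samples <- matrix(NA_real_, nrec, d)
  weights <- numeric(nrec)
  acc <- prop <- integer(d)
  r <- 0L
  for (i in seq_len(config$n_steps)) {
    j <- sample.int(d, 1)
    delta <- if (config$proposal == "uniform")
      config$sigma_q * (2 * stats::runif(1) - 1)
    else config$sigma_q * stats::rnorm(1)
    cand <- cur
    cand[j] <- cand[j] + delta
    prop[j] <- prop[j] + 1L
    if (cand[j] >= prior$lower[j] && cand[j] <= prior$upper[j]) {
      wc <- wfun(cand)
      if (wc > 0 && (wc >= wcur || stats::runif(1) < wc / wcur)) {
        cur <- cand; wcur <- wc; acc[j] <- acc[j] + 1L
      }
    }
    if (i > config$burn_in && (i - config$burn_in) %% config$thin == 0 &&
        r < nrec) {
      r <- r + 1L
      samples[r, ] <- cur
      weights[r] <- wcur
    }
  }
  list(samples = samples, weights = weights, accept = acc, propose = prop)
}

#' @export
print.hfm_fit <- function(x, ...) {
  cat(sprintf("MCMC-HFM fit: %d retained samples of (%s), %s engine\n",
              nrow(x$samples), paste(colnames(x$samples), collapse = ", "),
              x$engine))
  cat(sprintf("  %g steps, %g burn-in, thin %d, sigma_q %g (%s proposal)\n",
              x$config$n_steps, x$config$burn_in, x$config$thin,
              x$config$sigma_q, x$config$proposal))
  ar <- sum(x$accept) / max(1, sum(x$propose))
  cat(sprintf("  overall acceptance rate %.3f; %d condition(s), %d fitness measure(s)\n",
              ar, length(x$conditions), length(x$fitness)))
  invisible(x)
}

#' @export
as.matrix.hfm_fit <- function(x, ...) x$samples
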