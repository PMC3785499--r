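#' ODE model specification
#'
#' A model bundles the right-hand side of an autonomous ODE system with a
#' scalar input channel, the state and parameter names, an (optionally
#' analytic) Jacobian, and a default search box for steady-state location.
#' Two models ship with the package: the one-variable Hill-feedback toy model
#' ([toy_hill_model()]) and a two-variable bistable fixture
#' ([bistable2d_model()]) used to exercise multi-dimensional stability
#' analysis.  User models plug in through the same contract and can be
#' registered under a string key with [register_model()].
#'
#' @param key model key: `"toy"` or `"bistable2d"`, or a key previously
#'   registered with [register_model()].
#' @return an object of class `hfm_model`.
#' @export
hfm_model <- function(key) {
  switch(key,
         toy = toy_hill_model(),
         bistable2d = bistable2d_model(),
         {
           m <- .model_registry[[key]]
           if (is.null(m)) stop("unknown model key: ", key)
           m
         })
}

.model_registry <- new.env(parent = emptyenv())

#' Register a user-defined model under a string key
#'
#' @param key string key for later lookup via [hfm_model()] and the run
#'   config.
#' @param model an `hfm_model` built with [ode_model()].
#' @return the model, invisibly.
#' @export
register_model <- function(key, model) {
  stopifnot(is.character(key), length(key) == 1, inherits(model, "hfm_model"))
  assign(key, model, envir = .model_registry)
  invisible(model)
}

#' Build an ODE model from a right-hand-side function
#'
#' @param key short identifier.
#' @param state_names ordered state variable names.
#' @param input_name name of the scalar input channel.
#' @param param_names ordered names of the (inferable) kinetic parameters, in
#'   the order the `rhs` expects them.
#' @param rhs function `(y, pars, input) -> dy/dt` where `pars` is the named
#'   linear-scale parameter vector.
#' @param jacobian optional function with the same signature returning the
#'   square matrix of partial derivatives; a central finite difference is used
#'   when absent.
#' @param reference named linear-scale reference parameter values (used as the
#'   default chain start and to centre the default prior box).
#' @param fixed named constants held fixed (informational; the rhs closes over
#'   them).
#' @param default_box function `(pars, input) -> rbind(lo, hi)` giving a
#'   per-state bracket guaranteed to contain all steady states.
#' @param default_input default input level for dynamics simulations.
#' @return an object of class `hfm_model`.
#' @export
ode_model <- function(key, state_names, input_name, param_names, rhs,
                      jacobian = NULL, reference = NULL, fixed = NULL,
                      default_box = NULL, default_input = 0) {
  structure(list(key = key, state_names = state_names,
                 input_name = input_name, param_names = param_names,
                 d = length(state_names), rhs = rhs, jacobian = jacobian,
                 reference = reference, fixed = fixed,
                 default_box = default_box, default_input = default_input,
                 cpp_id = NA_integer_),
            class = "hfm_model")
}

#' @export
print.hfm_model <- function(x, ...) {
  cat(sprintf("ODE model '%s': states (%s), input %s, parameters (%s)\n",
              x$key, paste(x$state_names, collapse = ", "), x$input_name,
              paste(x$param_names, collapse = ", ")))
  if (!is.null(x$fixed))
    cat("  fixed:", paste(names(x$fixed), x$fixed, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' The one-variable Hill-feedback toy model
#'
#' A single protein Y is synthesized at the input rate \eqn{k_s}, degraded at
#' rate \eqn{k_d [Y]}, and up-regulates its own production through a
#' cooperative (Hill) positive feedback:
#' \deqn{d[Y]/dt = k_s - k_d [Y] + k_p [Y]^n / (K^n + [Y]^n), \quad n = 5.}
#' With the reference parameters \eqn{(k_d, k_p, K) = (1, 1, 0.5)} the system
#' is bistable for intermediate input and irreversible (the high branch
#' persists at \eqn{k_s = 0}); the saddle-node structure is the qualitative
#' signature used as a fitness measure.  The Hill coefficient is a fixed model
#' constant, not an inferred parameter.
#'
#' @return an `hfm_model` with parameters `k_d`, `k_p`, `K` and state `Y`.
#' @examples
#' m <- toy_hill_model()
#' m$rhs(0.5, c(k_d = 1, k_p = 1, K = 0.5), 1.0)  # = 1 at y = K
#' @export
toy_hill_model <- function() {
  n <- 5
  m <- ode_model(
    key = "toy", state_names = "Y", input_name = "k_s",
    param_names = c("k_d", "k_p", "K"),
    rhs = function(y, pars, input) {
      if (any(y < 0)) stop("negative state passed to toy model rhs")
      input - pars[["k_d"]] * y + pars[["k_p"]] * y^n / (pars[["K"]]^n + y^n)
    },
    jacobian = function(y, pars, input) {
      K5 <- pars[["K"]]^n
      matrix(-pars[["k_d"]] + pars[["k_p"]] * n * K5 * y^(n - 1) / (K5 + y^n)^2,
             1, 1)
    },
    reference = c(k_d = 1.0, k_p = 1.0, K = 0.5),
    fixed = c(n = n),
    # all roots satisfy k_d y = input + k_p h with h in [0, 1]
    default_box = function(pars, input)
      rbind(lo = 0, hi = (input + pars[["k_p"]]) / pars[["k_d"]] + 1),
    default_input = 1.0)
  m$cpp_id <- 1L
  m
}

#' Two-variable bistable fixture model
#'
#' A minimal two-state system with cooperative positive feedback,
#' \deqn{du/dt = input + \alpha v^2/(1 + v^2) - u, \qquad dv/dt = \beta u - v,}
#' bistable at `input = 0` with \eqn{\alpha = 3, \beta = 1} (steady states at
#' \eqn{v \in \{0, (3-\sqrt 5)/2, (3+\sqrt 5)/2\}}).  It exists to exercise
#' the multi-variable steady-state, Jacobian-eigenvalue and output-threshold
#' machinery that larger signalling models (e.g. caspase activation networks)
#' require; it is not a mechanistic model of any pathway.
#'
#' @return an `hfm_model` with parameters `alpha`, `beta` and states `u`, `v`.
#' @export
bistable2d_model <- function() {
  m <- ode_model(
    key = "bistable2d", state_names = c("u", "v"), input_name = "input",
    param_names = c("alpha", "beta"),
    rhs = function(y, pars, input) {
      if (any(y < 0)) stop("negative state passed to fixture rhs")
      c(input + pars[["alpha"]] * y[2]^2 / (1 + y[2]^2) - y[1],
        pars[["beta"]] * y[1] - y[2])
    },
    jacobian = function(y, pars, input) {
      v <- y[2]
      matrix(c(-1, pars[["beta"]],
               pars[["alpha"]] * 2 * v / (1 + v^2)^2, -1), 2, 2)
    },
    reference = c(alpha = 3, beta = 1),
    default_box = function(pars, input) {
      uhi <- input + pars[["alpha"]] + 1
      rbind(lo = c(0, 0), hi = c(uhi, pars[["beta"]] * uhi + 1))
    },
    default_input = 0)
  m$cpp_id <- 2L
  m
}

#' Right-hand side of the toy Hill-feedback model
#'
#' Convenience wrapper around [toy_hill_model()]'s rhs contract.
#'
#' @param y concentration of Y (non-negative scalar).
#' @param params an `hfm_params` (or named linear vector) with `k_d`, `k_p`, `K`.
#' @param k_s synthesis (input) rate.
#' @return dY/dt.
#' @export
toy_rhs <- function(y, params, k_s) {
  pars <- .linear_pars(params, c("k_d", "k_p", "K"))
  toy_hill_model()$rhs(y, pars, k_s)
}

#' Right-hand side of the two-variable fixture model
#'
#' @param state length-2 non-negative state vector `(u, v)`.
#' @param params an `hfm_params` (or named linear vector) with `alpha`, `beta`.
#' @param input scalar input added to du/dt.
#' @return length-2 derivative vector.
#' @export
fixture_rhs <- function(state, params, input) {
  pars <- .linear_pars(params, c("alpha", "beta"))
  bistable2d_model()$rhs(state, pars, input)
}

# accept hfm_params or a named linear vector; check required names
.linear_pars <- function(params, required) {
  pars <- if (inherits(params, "hfm_params")) linear_values(params) else params
  if (is.null(names(pars)) || !all(required %in% names(pars)))
    stop("missing parameter(s): ",
         paste(setdiff(required, names(pars)), collapse = ", "))
  pars
}

# linear parameter vector ordered as the model expects
.model_pars <- function(model, params) {
  pars <- .linear_pars(params, model$param_names)
  pars[model$param_names]
}
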