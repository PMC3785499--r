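#' Fixed-step fourth-order Runge-Kutta integration
#'
#' Integrates a model deterministically on a fixed grid with the classical
#' four-stage Runge-Kutta scheme.  Built-in models run through the compiled
#' kernel; user-registered models fall back to an R loop with identical
#' semantics.
#'
#' @param model an `hfm_model`.
#' @param params an `hfm_params` or named linear-scale parameter vector.
#' @param input scalar input level (e.g. `k_s` for the toy model).
#' @param y0 initial state vector; defaults to the origin.
#' @param t_end final time; must be a positive multiple of `dt`.
#' @param dt time step (default 0.01).
#' @return an `hfm_trajectory`: list with `times`, `states` (matrix with one
#'   column per state), `dt` and metadata.
#' @examples
#' tr <- integrate_rk4(toy_hill_model(), c(k_d = 1, k_p = 1, K = 0.5),
#'                     input = 1, t_end = 10)
#' tail(tr$states[, "Y"], 1)
#' @export
integrate_rk4 <- function(model, params, input, y0 = NULL, t_end = 100,
                          dt = 0.01) {
  .integrate(model, params, input, y0, t_end, dt, noise_sd = 0, seed = NULL)
}

#' Simulate with additive Gaussian noise
#'
#' A deterministic RK4 drift step followed, at every step, by an additive
#' Gaussian increment \eqn{\epsilon\sqrt{dt}} with
#' \eqn{\epsilon \sim N(0, \sigma^2)} per state component
#' (an Euler-Maruyama-style diffusion, so the per-model `noise_variance` has a
#' dt-robust meaning), after which states are clamped at zero.  With
#' `noise_variance = 0` the result is bitwise identical to [integrate_rk4()].
#'
#' @inheritParams integrate_rk4
#' @param noise_variance variance of the Gaussian noise term (the toy-model
#'   study used 1 and, as a sharper variant, 0.01).
#' @param seed optional RNG seed (`set.seed`) for reproducibility.
#' @return an `hfm_trajectory`; `$noise` records the rule, variance and seed.
#' @export
simulate_noisy <- function(model, params, input, y0 = NULL, t_end = 100,
                           dt = 0.01, noise_variance = 1, seed = NULL) {
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  .integrate(model, params, input, y0, t_end, dt,
             noise_sd = sqrt(noise_variance), seed = seed)
}

.integrate <- function(model, params, input, y0, t_end, dt, noise_sd, seed) {
  stopifnot(inherits(model, "hfm_model"))
  if (dt <= 0) stop("dt must be positive")
  nsteps <- round(t_end / dt)
  if (nsteps < 1 || abs(nsteps * dt - t_end) > 1e-9 * max(1, t_end))
    stop("t_end must be a positive multiple of dt")
  if (is.null(y0)) y0 <- rep(0, model$d)
  if (length(y0) != model$d || any(!is.finite(y0)))
    stop("y0 must be a finite vector of length ", model$d)
  pars <- .model_pars(model, params)
  states <- if (!is.na(model$cpp_id)) {
    cpp_rk4(model$cpp_id, unname(pars), input, as.numeric(y0), dt, nsteps,
            noise_sd)
  } else {
    .rk4_r(model, pars, input, as.numeric(y0), dt, nsteps, noise_sd)
  }
  colnames(states) <- model$state_names
  structure(list(times = seq(0, by = dt, length.out = nsteps + 1),
                 states = states, dt = dt, model = model$key, input = input,
                 noise = if (noise_sd > 0)
                   list(rule = "post-step additive eps*sqrt(dt), clamped at 0",
                        variance = noise_sd^2, seed = seed)),
            class = "hfm_trajectory")
}

# plain-R RK4 for user-registered models
.rk4_r <- function(model, pars, input, y0, dt, nsteps, noise_sd) {
  d <- length(y0)
  out <- matrix(NA_real_, nsteps + 1, d)
  y <- y0
  out[1, ] <- y
  f <- model$rhs
  sq <- noise_sd * sqrt(dt)
  for (i in seq_len(nsteps)) {
    k1 <- f(y, pars, input)
    k2 <- f(y + dt / 2 * k1, pars, input)
    k3 <- f(y + dt / 2 * k2, pars, input)
    k4 <- f(y + dt * k3, pars, input)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (noise_sd > 0) y <- pmax(y + sq * stats::rnorm(d), 0)
    if (any(!is.finite(y)))
      stop("non-finite state at integration step ", i)
    out[i + 1, ] <- y
  }
  out
}

#' @export
print.hfm_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s' (%d points, dt = %g, input = %g%s)\n",
              x$model, length(x$times), x$dt, x$input,
              if (is.null(x$noise)) "" else
                sprintf(", noise variance %g", x$noise$variance)))
  cat("final state:", paste(colnames(x$states),
                            signif(x$states[nrow(x$states), ], 6),
                            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.hfm_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = "concentration", ...)
  if (ncol(x$states) > 1)
    graphics::legend("bottomright", legend = colnames(x$states),
                     col = seq_len(ncol(x$states)), lty = 1, bty = "n")
  invisible(x)
}

#' Export a trajectory as CSV plus a JSON sidecar
#'
#' Writes `time,<state names>` rows to `path` and run metadata (model key,
#' input, dt, noise rule and seed) to `<path>.json`.
#'
#' @param traj an `hfm_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hfm_trajectory"))
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model = traj$model, input = traj$input, dt = traj$dt,
               noise = traj$noise)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
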