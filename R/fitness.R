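#' Scalar observables extracted from trajectories
#'
#' Observable descriptors name a scalar quantity computed from a simulated
#' trajectory (or directly from the parameter vector) so that quantitative
#' fitness measures can refer to it declaratively:
#'
#' * `obs_execution_time()`: first time the named state reaches `fraction`
#'   (default 90 percent) of its trajectory maximum.
#' * `obs_switching_time()`: duration between the first crossings of `lo`
#'   (2.5 percent) and `hi` (97.5 percent) of the trajectory maximum.
#' * `obs_endpoint()`: state value at a fixed time on the grid.
#' * `obs_parameter()`: the current value of a sampled parameter itself, on
#'   the log10 or linear scale (no dynamics needed); useful for prior
#'   shaping and for validating the sampler against tabulated targets.
#'
#' @param state state variable name.
#' @param fraction threshold fraction of the maximum (execution time).
#' @param lo,hi lower/upper threshold fractions (switching time).
#' @param time trajectory time at which to read the state (endpoint).
#' @param name sampled parameter name (parameter observable).
#' @param scale `"log10"` or `"linear"` (parameter observable).
#' @return an `hfm_observable` descriptor.
#' @export
obs_execution_time <- function(state, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  .obs("execution_time", state = state, p1 = fraction, code = 0L)
}

#' @rdname obs_execution_time
#' @export
obs_switching_time <- function(state, lo = 0.025, hi = 0.975) {
  stopifnot(lo > 0, lo < hi, hi < 1)
  .obs("switching_time", state = state, p1 = lo, p2 = hi, code = 2L)
}

#' @rdname obs_execution_time
#' @export
obs_endpoint <- function(state, time = 100) {
  .obs("endpoint", state = state, p1 = time, code = 1L)
}

#' @rdname obs_execution_time
#' @export
obs_parameter <- function(name, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  .obs("parameter", param = name, code = if (scale == "log10") 3L else 4L)
}

.obs <- function(kind, state = NA_character_, param = NA_character_,
                 p1 = 0, p2 = 0, code) {
  structure(list(kind = kind, state = state, param = param,
                 p1 = p1, p2 = p2, code = code), class = "hfm_observable")
}

#' @export
print.hfm_observable <- function(x, ...) {
  cat("observable:", obs_label(x), "\n")
  invisible(x)
}

obs_label <- function(o) {
  switch(o$kind,
         execution_time = sprintf("execution time of %s (%g%% of max)",
                                  o$state, 100 * o$p1),
         switching_time = sprintf("switching time of %s (%g%%-%g%% of max)",
                                  o$state, 100 * o$p1, 100 * o$p2),
         endpoint = sprintf("[%s] at time = %g", o$state, o$p1),
         parameter = sprintf("parameter %s (%s)", o$param,
                             if (o$code == 3L) "log10" else "linear"))
}

#' Evaluate an observable on a trajectory
#'
#' `execution_time()` returns the first grid time at which the state reaches
#' `fraction` of its maximum over the trajectory grid; `switching_time()`
#' the gap between the first crossings of the `lo` and `hi` fractions;
#' `endpoint_value()` the state value at time `t`.  First-crossing times use
#' the discrete grid with no interpolation, so a constant trajectory
#' (including the all-zero one) reports time 0.
#'
#' @param traj an `hfm_trajectory`.
#' @param state state variable name.
#' @param fraction,lo,hi threshold fractions of the trajectory maximum.
#' @param t time on the trajectory grid.
#' @return a scalar time, duration or concentration.
#' @examples
#' tr <- integrate_rk4(toy_hill_model(), c(k_d = 1, k_p = 1, K = 0.5),
#'                     input = 1, t_end = 100)
#' execution_time(tr, "Y")
#' endpoint_value(tr, "Y", 100)
#' @export
execution_time <- function(traj, state, fraction = 0.9) {
  y <- .traj_col(traj, state)
  thr <- fraction * max(y)
  traj$times[which(y >= thr)[1]]
}

#' @rdname execution_time
#' @export
switching_time <- function(traj, state, lo = 0.025, hi = 0.975) {
  stopifnot(lo > 0, lo < hi, hi < 1)
  y <- .traj_col(traj, state)
  m <- max(y)
  t_lo <- traj$times[which(y >= lo * m)[1]]
  t_hi <- traj$times[which(y >= hi * m)[1]]
  t_hi - t_lo
}

#' @rdname execution_time
#' @export
endpoint_value <- function(traj, state, t = 100) {
  y <- .traj_col(traj, state)
  idx <- which(abs(traj$times - t) < traj$dt / 2)
  if (!length(idx)) stop("time ", t, " is beyond the trajectory grid")
  y[idx[1]]
}

.traj_col <- function(traj, state) {
  stopifnot(inherits(traj, "hfm_trajectory"))
  if (!state %in% colnames(traj$states))
    stop("unknown state name: ", state)
  traj$states[, state]
}

#' Histogram-valued quantitative fitness measure
#'
#' The fitness of a simulated observable value is the recorded frequency of
#' the histogram bin it falls in — raw counts, not densities, since only
#' ratios enter the Metropolis acceptance probability.  Bins are half-open
#' `[edge_i, edge_{i+1})` with the last bin closed on the right; values
#' outside the edge range score 0.
#'
#' @param observable an `hfm_observable` descriptor.
#' @param bin_edges strictly increasing numeric vector of bin edges.
#' @param frequencies non-negative per-bin frequencies,
#'   `length(bin_edges) - 1` of them, at least one positive.
#' @return an object of class `hfm_fitness` (subtype `"histogram"`).
#' @export
histogram_fitness <- function(observable, bin_edges, frequencies) {
  stopifnot(inherits(observable, "hfm_observable"))
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (length(frequencies) != length(bin_edges) - 1)
    stop("need length(bin_edges) - 1 frequencies")
  if (any(frequencies < 0) || !any(frequencies > 0))
    stop("frequencies must be non-negative with at least one positive entry")
  structure(list(type = "histogram", observable = observable,
                 bin_edges = as.numeric(bin_edges),
                 frequencies = as.numeric(frequencies)),
            class = "hfm_fitness")
}

#' Log-normal quantitative fitness measure from mean and SD
#'
#' Parameterizes a log-normal density by the desired expected value and
#' standard deviation of the observable (e.g. a switching time of 23 +/- 10
#' minutes), via [lognormal_from_moments()].  The fitness of a simulated
#' value is the density at that value; non-positive values score 0.
#'
#' @inheritParams histogram_fitness
#' @param mean expected value of the observable (must be positive).
#' @param sd standard deviation of the observable (must be positive).
#' @return an `hfm_fitness` (subtype `"lognormal"`) with derived log-scale
#'   parameters `mu` and `sigma`.
#' @export
lognormal_fitness <- function(observable, mean, sd) {
  stopifnot(inherits(observable, "hfm_observable"))
  ms <- lognormal_from_moments(mean, sd)
  structure(list(type = "lognormal", observable = observable,
                 mean = mean, sd = sd, mu = ms[["mu"]], sigma = ms[["sigma"]]),
            class = "hfm_fitness")
}

#' Moment inversion for the log-normal distribution
#'
#' Solves for the log-scale parameters giving a log-normal variable the
#' requested mean and standard deviation:
#' \eqn{\sigma^2 = \log(1 + sd^2/mean^2)}, \eqn{\mu = \log(mean) - \sigma^2/2}.
#'
#' @param mean,sd desired moments; both must be positive.
#' @return named vector `c(mu = ..., sigma = ...)`.
#' @examples
#' lognormal_from_moments(23, 10)
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("mean and sd must be positive")
  s2 <- log(1 + sd^2 / mean^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Evaluate a quantitative fitness measure at an observable value
#'
#' @param f an `hfm_fitness`.
#' @param z simulated observable value.
#' @return a non-negative weight (bin frequency or density).
#' @export
eval_fitness <- function(f, z) {
  stopifnot(inherits(f, "hfm_fitness"))
  if (!is.finite(z)) return(0)
  if (f$type == "histogram") {
    e <- f$bin_edges
    if (z < e[1] || z > e[length(e)]) return(0)
    if (z == e[length(e)]) return(f$frequencies[length(f$frequencies)])
    f$frequencies[findInterval(z, e)]
  } else {
    if (z <= 0) return(0)
    stats::dlnorm(z, meanlog = f$mu, sdlog = f$sigma)
  }
}

#' @export
print.hfm_fitness <- function(x, ...) {
  if (x$type == "histogram")
    cat(sprintf("Histogram fitness on %s: %d bins over [%g, %g], total frequency %g\n",
                obs_label(x$observable), length(x$frequencies),
                x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
                sum(x$frequencies)))
  else
    cat(sprintf("Log-normal fitness on %s: mean %g, sd %g (mu %.4f, sigma %.4f)\n",
                obs_label(x$observable), x$mean, x$sd, x$mu, x$sigma))
  invisible(x)
}

#' Read and write histogram fitness files
#'
#' Histogram fitness measures are exchanged as CSV with columns
#' `bin_left,bin_right,frequency` plus a JSON sidecar (`<path>.json`)
#' recording the observable descriptor and, when generated synthetically,
#' the generator settings.
#'
#' @param f an `hfm_fitness` of subtype `"histogram"`.
#' @param path CSV path.
#' @return `write_histogram_fitness()` returns `path` invisibly;
#'   `read_histogram_fitness()` returns the reconstructed `hfm_fitness`.
#' @export
write_histogram_fitness <- function(f, path) {
  stopifnot(inherits(f, "hfm_fitness"), f$type == "histogram")
  n <- length(f$frequencies)
  utils::write.csv(data.frame(bin_left = f$bin_edges[-(n + 1)],
                              bin_right = f$bin_edges[-1],
                              frequency = f$frequencies),
                   path, row.names = FALSE)
  meta <- list(observable = unclass(f$observable),
               generator = attr(f, "generator"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_histogram_fitness
#' @export
read_histogram_fitness <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("bin_left", "bin_right", "frequency") %in% names(df)))
    stop("histogram CSV needs columns bin_left, bin_right, frequency")
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  o <- meta$observable
  obs <- structure(list(kind = o$kind, state = o$state, param = o$param,
                        p1 = o$p1, p2 = o$p2, code = as.integer(o$code)),
                   class = "hfm_observable")
  f <- histogram_fitness(obs, c(df$bin_left, df$bin_right[nrow(df)]),
                         df$frequency)
  attr(f, "generator") <- meta$generator
  f
}
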