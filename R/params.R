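#' Named kinetic parameter vector on a common-log scale
#'
#' Kinetic parameters are stored as common logarithms (log10) of their linear
#' values, together with a box prior: per-parameter lower and upper bounds on
#' the log10 scale.  By default the box spans one decade either side of the
#' supplied values (tenfold and one-tenth), the conventional choice for
#' log-uniform priors over rate constants.
#'
#' @param values named numeric vector of parameter values.  Interpreted on the
#'   linear scale unless `log10 = TRUE`.
#' @param lower,upper optional per-parameter bounds (same scale convention as
#'   `values`); recycled if length 1.  Defaults to `values/factor` and
#'   `values*factor`.
#' @param factor width of the default prior box on the linear scale.
#' @param log10 logical; are `values` (and bounds, if given) already log10?
#' @return an object of class `hfm_params` with fields `names`, `log10`
#'   (log10 values), `lower` and `upper` (log10 bounds).
#' @examples
#' theta <- param_vector(c(k_d = 1, k_p = 1, K = 0.5))
#' linear_values(theta)
#' in_prior_box(theta)
#' @export
param_vector <- function(values, lower = NULL, upper = NULL, factor = 10,
                         log10 = FALSE) {
  nm <- names(values)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("`values` must have unique, non-empty names")
  v <- as.numeric(values)
  if (!log10) {
    if (any(v <= 0)) stop("linear parameter values must be positive")
    v <- log10(v)
  }
  lo <- if (is.null(lower)) v - log10(factor) else
    (if (log10) rep_len(as.numeric(lower), length(v)) else
       log10(rep_len(as.numeric(lower), length(v))))
  up <- if (is.null(upper)) v + log10(factor) else
    (if (log10) rep_len(as.numeric(upper), length(v)) else
       log10(rep_len(as.numeric(upper), length(v))))
  if (any(lo >= up)) {
    bad <- nm[lo >= up]
    stop("lower bound must be below upper bound for: ", paste(bad, collapse = ", "))
  }
  structure(list(names = nm, log10 = stats::setNames(v, nm),
                 lower = stats::setNames(lo, nm),
                 upper = stats::setNames(up, nm)),
            class = "hfm_params")
}

#' @export
print.hfm_params <- function(x, ...) {
  cat("Kinetic parameters (log10 scale, box prior):\n")
  print(data.frame(log10 = x$log10, linear = 10^x$log10,
                   lower = x$lower, upper = x$upper, row.names = x$names))
  invisible(x)
}

#' Linear-scale parameter values
#' @param p an `hfm_params` object.
#' @return named numeric vector `10^log10`.
#' @export
linear_values <- function(p) {
  stopifnot(inherits(p, "hfm_params"))
  stats::setNames(10^p$log10, p$names)
}

#' Is each coordinate inside the prior box?
#' @param p an `hfm_params` object.
#' @param log10_values optional log10 vector to test against `p`'s bounds
#'   (defaults to `p`'s own values).
#' @return named logical vector, one entry per parameter.
#' @export
in_prior_box <- function(p, log10_values = NULL) {
  stopifnot(inherits(p, "hfm_params"))
  v <- if (is.null(log10_values)) p$log10 else as.numeric(log10_values)
  stats::setNames(v >= p$lower & v <= p$upper, p$names)
}

# replace the values of a parameter vector, keeping its bounds
set_log10_values <- function(p, log10_values) {
  p$log10 <- stats::setNames(as.numeric(log10_values), p$names)
  p
}
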