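#' Marginal posterior summary for one parameter
#'
#' Histograms the retained log10 samples of one parameter over its prior
#' range, reports the mode as the centre of the maximal-probability bin
#' (leftmost on ties), and the 95% credible interval as the empirical
#' 2.5%/97.5% quantiles (nearest rank on the sorted sample), reported on the
#' linear scale together with the common logarithm of the upper/lower bound
#' ratio — the credibility width used throughout.
#'
#' @param fit an `hfm_fit`, or a matrix of log10 samples with named columns
#'   (then `range` must be supplied).
#' @param parameter parameter name.
#' @param n_bins number of equal-width bins over the prior range.
#' @param level credible level (default 0.95).
#' @param range optional `c(lower, upper)` log10 histogram range; defaults
#'   to the prior bounds stored in the fit.
#' @return an object of class `hfm_marginal`: list with `parameter`,
#'   `bin_edges`, `probabilities` (summing to 1), `mode_log10`, `mode`
#'   (linear), `ci` (linear lower/upper) and `log10_width`.
#' @export
marginal_summary <- function(fit, parameter, n_bins = 50, level = 0.95,
                             range = NULL) {
  x <- .fit_samples(fit)
  if (!parameter %in% colnames(x)) stop("unknown parameter: ", parameter)
  v <- x[, parameter]
  if (is.null(range)) {
    if (!inherits(fit, "hfm_fit"))
      stop("supply `range` when summarizing a bare sample matrix")
    range <- c(fit$prior$lower[[parameter]], fit$prior$upper[[parameter]])
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L; idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, n_bins)
  probs <- counts / length(v)
  mode_bin <- which.max(probs)  # which.max takes the leftmost tie
  mode_log10 <- (edges[mode_bin] + edges[mode_bin + 1]) / 2
  s <- sort(v)
  n <- length(s)
  alpha <- (1 - level) / 2
  ci_lo <- 10^s[max(1, ceiling(alpha * n))]
  ci_hi <- 10^s[max(1, ceiling((1 - alpha) * n))]
  structure(list(parameter = parameter, bin_edges = edges,
                 probabilities = probs, mode_log10 = mode_log10,
                 mode = 10^mode_log10, ci = c(lower = ci_lo, upper = ci_hi),
                 log10_width = log10(ci_hi / ci_lo), level = level),
            class = "hfm_marginal")
}

#' @export
print.hfm_marginal <- function(x, ...) {
  cat(sprintf("%s: mode %.4g (log10 %.3f), %g%% CI [%.4g, %.4g], log10 width %.3f\n",
              x$parameter, x$mode, x$mode_log10, 100 * x$level,
              x$ci[["lower"]], x$ci[["upper"]], x$log10_width))
  invisible(x)
}

.fit_samples <- function(fit) {
  if (inherits(fit, "hfm_fit")) fit$samples
  else if (is.matrix(fit) && !is.null(colnames(fit))) fit
  else stop("expected an hfm_fit or a column-named sample matrix")
}

#' Summarize a hybrid-fitness MCMC fit
#'
#' @param object an `hfm_fit`.
#' @param n_bins marginal histogram bins over the prior box.
#' @param level credible level.
#' @param ... unused.
#' @return a `summary.hfm_fit`: data frame of per-parameter modes, credible
#'   intervals and log10 widths, plus acceptance rates.
#' @export
summary.hfm_fit <- function(object, n_bins = 50, level = 0.95, ...) {
  ms <- lapply(colnames(object$samples), function(p)
    marginal_summary(object, p, n_bins = n_bins, level = level))
  tab <- do.call(rbind, lapply(ms, function(m)
    data.frame(parameter = m$parameter, mode = m$mode,
               mode_log10 = m$mode_log10, ci_lower = m$ci[["lower"]],
               ci_upper = m$ci[["upper"]], log10_width = m$log10_width)))
  rownames(tab) <- tab$parameter
  structure(list(table = tab, marginals = ms,
                 acceptance = object$accept / pmax(1, object$propose),
                 n_samples = nrow(object$samples), level = level),
            class = "summary.hfm_fit")
}

#' @export
print.summary.hfm_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%d samples, %g%% credible intervals):\n",
              x$n_samples, 100 * x$level))
  print(x$table[, -1], digits = 4)
  cat("per-parameter acceptance rates:",
      paste(names(x$acceptance), signif(x$acceptance, 3), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn summary.hfm_fit marginal modes on the linear scale — the
#'   representative inferred parameter values.
#' @export
coef.hfm_fit <- function(object, n_bins = 50, ...) {
  s <- summary(object, n_bins = n_bins)
  stats::setNames(s$table$mode, s$table$parameter)
}

#' @describeIn summary.hfm_fit credible intervals (linear scale).
#' @param parm parameters to include (default all).
#' @export
confint.hfm_fit <- function(object, parm, level = 0.95, ...) {
  nms <- colnames(object$samples)
  if (!missing(parm)) nms <- intersect(nms, parm)
  out <- t(vapply(nms, function(p)
    marginal_summary(object, p, level = level)$ci, numeric(2)))
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' Plot marginal posterior histograms
#'
#' One panel per parameter: the discrete marginal probability distribution
#' on the log10 scale, with the mode arrow and optional reference values.
#'
#' @param x an `hfm_fit`.
#' @param n_bins histogram bins.
#' @param truth optional named vector of linear-scale reference values drawn
#'   as vertical lines.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.hfm_fit <- function(x, n_bins = 50, truth = NULL, ...) {
  nms <- colnames(x$samples)
  old <- graphics::par(mfrow = c(1, length(nms)))
  on.exit(graphics::par(old))
  for (p in nms) {
    m <- marginal_summary(x, p, n_bins = n_bins)
    mids <- (m$bin_edges[-1] + m$bin_edges[-length(m$bin_edges)]) / 2
    bp <- graphics::barplot(m$probabilities, names.arg = signif(mids, 2),
                            main = p, xlab = paste0("log10 ", p),
                            ylab = "probability", border = NA, ...)
    if (!is.null(truth) && p %in% names(truth))
      graphics::abline(v = bp[which.min(abs(mids - log10(truth[[p]])))],
                       col = 2, lwd = 2)
  }
  invisible(x)
}

#' Pearson correlations between inferred parameters
#'
#' Correlation coefficients between the retained log10 samples of each
#' parameter pair, as used to read off compensating parameter combinations.
#'
#' @param fit an `hfm_fit` or column-named log10 sample matrix.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   parameters yield `NA` entries with a warning.
#' @export
correlation_matrix <- function(fit) {
  x <- .fit_samples(fit)
  if (nrow(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance parameter(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(x))
}

#' Joint 2-D posterior histogram of a parameter pair
#'
#' @param fit an `hfm_fit`.
#' @param param_a,param_b parameter names.
#' @param n_bins bins per axis over each prior range.
#' @return list with `edges_a`, `edges_b` and `probabilities` (an
#'   `n_bins x n_bins` matrix summing to 1).
#' @export
joint_histogram <- function(fit, param_a, param_b, n_bins = 50) {
  stopifnot(inherits(fit, "hfm_fit"))
  x <- fit$samples
  mk <- function(p) seq(fit$prior$lower[[p]], fit$prior$upper[[p]],
                        length.out = n_bins + 1)
  ea <- mk(param_a); eb <- mk(param_b)
  bin <- function(v, e) {
    i <- findInterval(v, e, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), n_bins)
  }
  ia <- bin(x[, param_a], ea); ib <- bin(x[, param_b], eb)
  tab <- matrix(0, n_bins, n_bins)
  for (k in seq_along(ia)) tab[ia[k], ib[k]] <- tab[ia[k], ib[k]] + 1
  list(edges_a = ea, edges_b = eb, probabilities = tab / nrow(x))
}

#' Posterior-predictive histogram of a trajectory observable
#'
#' Re-simulates the deterministic dynamics for a uniform sub-sample of the
#' retained parameter vectors and histograms the requested observable — the
#' check that inferred parameters reproduce the data histograms.
#'
#' @param fit an `hfm_fit` whose model supports simulation.
#' @param observable an `hfm_observable` (trajectory kind).
#' @param n_bins histogram bins.
#' @param subsample number of parameter vectors to re-simulate (drawn
#'   uniformly without replacement when the trace is larger).
#' @param breaks optional explicit bin edges (e.g. those of the fitness
#'   histogram, for bin-by-bin comparison).
#' @return an `hfm_fitness` histogram over the predicted observable values.
#' @export
observable_histogram <- function(fit, observable, n_bins = 50,
                                 subsample = 1e4, breaks = NULL) {
  stopifnot(inherits(fit, "hfm_fit"), inherits(observable, "hfm_observable"),
            observable$code <= 2L)
  if (is.null(fit$model)) stop("fit has no model to re-simulate")
  x <- fit$samples
  if (nrow(x) > subsample)
    x <- x[sample.int(nrow(x), subsample), , drop = FALSE]
  st <- match(observable$state, fit$model$state_names) - 1L
  if (is.na(st)) stop("unknown state name: ", observable$state)
  vals <- if (!is.na(fit$model$cpp_id)) {
    cpp_predict_observables(fit$model$cpp_id, x, fit$sim$input,
                            as.numeric(fit$sim$y0), fit$sim$dt,
                            as.integer(fit$sim$nsteps), observable$code, st,
                            observable$p1, observable$p2)[, 1]
  } else {
    apply(x, 1, function(v) {
      tr <- integrate_rk4(fit$model, set_log10_values(fit$prior, v),
                          fit$sim$input, fit$sim$y0, fit$sim$t_end,
                          fit$sim$dt)
      switch(observable$kind,
             execution_time = execution_time(tr, observable$state, observable$p1),
             switching_time = switching_time(tr, observable$state,
                                             observable$p1, observable$p2),
             endpoint = endpoint_value(tr, observable$state, observable$p1))
    })
  }
  vals <- vals[is.finite(vals)]
  .histogram_from_values(observable, vals, n_bins, breaks)
}

#' @describeIn observable_histogram `predict()` alias; returns the
#'   posterior-predictive histogram.
#' @param object an `hfm_fit`.
#' @param ... passed on to `observable_histogram()`.
#' @export
predict.hfm_fit <- function(object, observable, ...) {
  observable_histogram(object, observable, ...)
}

# equal-width histogram over the value range (single-point samples get a
# tiny symmetric bin so the histogram stays well-formed)
.histogram_from_values <- function(observable, vals, n_bins, breaks = NULL) {
  if (!length(vals)) stop("no finite observable values to histogram")
  if (is.null(breaks)) {
    r <- range(vals)
    if (r[1] == r[2]) r <- r + c(-1, 1) * max(1e-8, abs(r[1]) * 1e-8)
    breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  }
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(breaks) - 1
  counts <- tabulate(idx[keep], length(breaks) - 1)
  histogram_fitness(observable, breaks, counts)
}
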