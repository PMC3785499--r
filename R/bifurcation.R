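#' Locate all steady states of a model at a given input level
#'
#' Solves `rhs(y) = 0` and classifies each root by the eigenvalues of the
#' Jacobian.  For one-state models the primary finder is dense grid
#' bracketing (sign changes refined by bisection and polished by Newton),
#' which is exhaustive up to the grid resolution; for two or more states a
#' multi-start Newton-Raphson iteration from a regular grid of starting
#' points is used.  Converged roots are re-verified (`max |rhs| <= 1e-10`),
#' deduplicated within a radius of `1e-6`, and sorted by the first state
#' coordinate.
#'
#' @param model an `hfm_model`.
#' @param params an `hfm_params` or named linear-scale parameter vector.
#' @param input scalar input level.
#' @param search_box optional `rbind(lo, hi)` per-state bracket; defaults to
#'   the model's own box, which is guaranteed to contain all steady states.
#' @param n_starts Newton starting points per state dimension (multi-start
#'   method).
#' @param n_grid grid resolution for the 1-D bracketing finder.
#' @param method `"auto"` (bracketing for 1-D, Newton otherwise),
#'   `"bracket"` (1-D only) or `"newton"`.
#' @return an `hfm_steady_states` object: a list of steady states, each with
#'   `state` (named vector), `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"`, from the sign of the largest real eigenvalue part with a
#'   `1e-8` marginal band) and `eigenvalues`.  Empty when no start converges.
#' @examples
#' ss <- find_steady_states(toy_hill_model(), c(k_d = 1, k_p = 1, K = 0.5), 0.2)
#' sapply(ss, `[[`, "stability")
#' @export
find_steady_states <- function(model, params, input, search_box = NULL,
                               n_starts = 50, n_grid = 10000,
                               method = c("auto", "bracket", "newton")) {
  stopifnot(inherits(model, "hfm_model"))
  method <- match.arg(method)
  pars <- .model_pars(model, params)
  if (is.null(search_box)) {
    if (is.null(model$default_box))
      stop("model has no default search box; supply `search_box`")
    search_box <- model$default_box(pars, input)
  }
  if (any(!is.finite(search_box))) stop("search_box must be finite")
  lo <- as.numeric(search_box[1, ]); hi <- as.numeric(search_box[2, ])
  if (method == "auto") method <- if (model$d == 1) "bracket" else "newton"
  if (method == "bracket" && model$d != 1)
    stop("bracketing finder requires a one-state model")

  if (!is.na(model$cpp_id)) {
    if (method == "bracket") {
      m <- cpp_steady_1d(model$cpp_id, unname(pars), input, lo, hi, n_grid)
      states <- matrix(m[, 1], ncol = 1)
      eig <- matrix(as.complex(m[, 2]), ncol = 1)
      max_re <- m[, 2]
    } else {
      r <- cpp_steady_nd(model$cpp_id, unname(pars), input, lo, hi, n_starts)
      states <- r$states
      eig <- matrix(complex(real = r$eig_re, imaginary = r$eig_im),
                    nrow = nrow(r$states))
      max_re <- r$max_re
    }
  } else {
    r <- .steady_r(model, pars, input, lo, hi, n_starts, n_grid, method)
    states <- r$states; eig <- r$eig; max_re <- r$max_re
  }
  out <- lapply(seq_len(nrow(states)), function(i) {
    list(state = stats::setNames(states[i, ], model$state_names),
         stability = .stability_label(max_re[i]),
         eigenvalues = eig[i, ])
  })
  structure(out, class = "hfm_steady_states", input = input, model = model$key)
}

.stability_label <- function(max_re, band = 1e-8) {
  if (abs(max_re) < band) "marginal" else if (max_re < 0) "stable" else "unstable"
}

# R fallback finder for user-registered models
.steady_r <- function(model, pars, input, lo, hi, n_starts, n_grid, method) {
  d <- model$d
  roots <- list()
  if (method == "bracket") {
    g <- seq(lo, hi, length.out = n_grid + 1)
    fv <- vapply(g, function(y) model$rhs(y, pars, input), numeric(1))
    cand <- g[fv == 0]
    sc <- which(fv[-length(fv)] * fv[-1] < 0)
    for (i in sc)
      cand <- c(cand, stats::uniroot(function(y) model$rhs(y, pars, input),
                                     c(g[i], g[i + 1]), tol = 1e-13)$root)
    roots <- lapply(sort(cand), function(x) x)
  } else {
    grid1 <- function(j) if (n_starts == 1) mean(c(lo[j], hi[j])) else
      seq(lo[j], hi[j], length.out = n_starts)
    starts <- as.matrix(expand.grid(lapply(seq_len(d), grid1)))
    for (s in seq_len(nrow(starts))) {
      y <- starts[s, ]
      ok <- FALSE
      for (it in 1:100) {
        f <- model$rhs(y, pars, input)
        if (any(!is.finite(f))) break
        if (max(abs(f)) <= 1e-10) { ok <- TRUE; break }
        J <- .jac_at(model, y, pars, input)
        step <- tryCatch(solve(J, -f), error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        y <- y + step
      }
      if (ok) roots <- c(roots, list(y))
    }
  }
  # verify, dedup, sort
  keep <- list()
  for (y in roots) {
    if (any(y < lo - 1e-9 | y > hi + 1e-9)) next
    if (max(abs(model$rhs(y, pars, input))) > 1e-10) next
    if (!any(vapply(keep, function(k) sqrt(sum((k - y)^2)) < 1e-6, logical(1))))
      keep <- c(keep, list(y))
  }
  keep <- keep[order(vapply(keep, `[`, numeric(1), 1))]
  states <- do.call(rbind, c(keep, list(matrix(numeric(0), 0, d))))
  eig <- matrix(NA_complex_, nrow(states), d)
  max_re <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    ev <- eigen(.jac_at(model, states[i, ], pars, input),
                only.values = TRUE)$values
    eig[i, ] <- ev
    max_re[i] <- max(Re(ev))
  }
  list(states = states, eig = eig, max_re = max_re)
}

.jac_at <- function(model, y, pars, input, h = 1e-6) {
  if (!is.null(model$jacobian))
    return(matrix(model$jacobian(y, pars, input), model$d, model$d))
  d <- model$d
  J <- matrix(NA_real_, d, d)
  for (j in seq_len(d)) {
    e <- rep(0, d); e[j] <- h
    yp <- pmax(y + e, 0); ym <- pmax(y - e, 0)
    J[, j] <- (model$rhs(yp, pars, input) - model$rhs(ym, pars, input)) /
      (yp[j] - ym[j])
  }
  J
}

#' @export
print.hfm_steady_states <- function(x, ...) {
  cat(sprintf("%d steady state(s) at input = %g (model '%s')\n",
              length(x), attr(x, "input"), attr(x, "model")))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.hfm_steady_states <- function(x, ...) {
  df <- do.call(rbind, lapply(x, function(s)
    data.frame(t(s$state), stability = s$stability,
               max_re_eigenvalue = max(Re(s$eigenvalues)))))
  if (is.null(df)) df <- data.frame()
  df
}

#' Classify the local stability of a verified steady state
#'
#' Evaluates the Jacobian at `state` (analytic when the model provides one,
#' otherwise central finite differences) and labels the state from the sign
#' of the largest real part of its eigenvalues, with a `band`-wide marginal
#' zone around zero.
#'
#' @inheritParams find_steady_states
#' @param state state vector at (or very near) equilibrium.
#' @param band half-width of the marginal band on the real axis.
#' @return list with `stability` and `eigenvalues`.
#' @export
classify_stability <- function(model, params, input, state, band = 1e-8) {
  pars <- .model_pars(model, params)
  J <- .jac_at(model, state, pars, input)
  if (any(!is.finite(J))) stop("non-finite Jacobian at supplied state")
  ev <- eigen(J, only.values = TRUE)$values
  list(stability = .stability_label(max(Re(ev)), band), eigenvalues = ev)
}

#' Declarative bifurcation-pattern condition (qualitative fitness)
#'
#' A condition is a conjunction of clauses; each clause demands an exact
#' number of stable and unstable steady states at one input level, optionally
#' with output thresholds on selected stable branches.  Evaluating the
#' condition yields the 0/1 indicator used as a qualitative fitness measure.
#'
#' @param name short identifier (e.g. `"B"` for bistability).
#' @param clauses list of clauses built with [clause()].
#' @return an object of class `hfm_condition`.
#' @seealso [bistability_condition()], [irreversibility_condition()],
#'   [evaluate_condition()]
#' @export
condition_spec <- function(name, clauses) {
  stopifnot(is.character(name), length(clauses) >= 1,
            all(vapply(clauses, inherits, logical(1), "hfm_clause")))
  structure(list(name = name, clauses = clauses), class = "hfm_condition")
}

#' @rdname condition_spec
#' @param input input level at which the clause applies.
#' @param n_stable,n_unstable exact required counts of stable and unstable
#'   steady states.
#' @param thresholds optional list of threshold constraints from
#'   [state_threshold()].
#' @export
clause <- function(input, n_stable, n_unstable = 0, thresholds = list()) {
  structure(list(input = input, n_stable = as.integer(n_stable),
                 n_unstable = as.integer(n_unstable), thresholds = thresholds),
            class = "hfm_clause")
}

#' @rdname condition_spec
#' @param state state name the threshold constrains.
#' @param branch which stable branch: `"lower"` (smallest value of `state`
#'   among stable steady states) or `"higher"` (largest).
#' @param cmp comparator, `"<="` or `">="`.
#' @param value threshold value (e.g. 1.0 nM for a low inactive branch).
#' @export
state_threshold <- function(state, branch = c("lower", "higher"),
                            cmp = c("<=", ">="), value) {
  structure(list(state = state, branch = match.arg(branch),
                 cmp = match.arg(cmp), value = value),
            class = "hfm_threshold")
}

#' @export
print.hfm_condition <- function(x, ...) {
  cat(sprintf("Condition '%s' (%d clause(s)):\n", x$name, length(x$clauses)))
  for (cl in x$clauses)
    cat(sprintf("  input = %g: %d stable + %d unstable%s\n", cl$input,
                cl$n_stable, cl$n_unstable,
                if (length(cl$thresholds))
                  sprintf(", %d threshold(s)", length(cl$thresholds)) else ""))
  invisible(x)
}

#' Built-in qualitative conditions for the toy model
#'
#' `bistability_condition()` ("B") requires two stable plus one unstable
#' steady state at `k_s = 0.2` and a single stable state at `k_s = 0.3` and
#' `k_s = 1.0`.  `irreversibility_condition()` ("I") additionally requires
#' the bistable pattern to persist at `k_s = 0` (the high branch survives
#' when the input is removed).
#'
#' @return an `hfm_condition`.
#' @export
bistability_condition <- function() {
  condition_spec("B", list(clause(0.2, 2, 1), clause(0.3, 1, 0),
                           clause(1.0, 1, 0)))
}

#' @rdname bistability_condition
#' @export
irreversibility_condition <- function() {
  condition_spec("I", list(clause(0.2, 2, 1), clause(0.3, 1, 0),
                           clause(1.0, 1, 0), clause(0.0, 2, 1)))
}

#' Evaluate a qualitative condition to its 0/1 indicator
#'
#' Returns 1 only if, for every clause, the exact stable/unstable steady-state
#' counts match and all branch thresholds hold.  Any marginal steady state,
#' and any numerical failure during root finding, conservatively yields 0
#' (the latter with a warning).
#'
#' @param spec an `hfm_condition`.
#' @inheritParams find_steady_states
#' @return integer 0 or 1.
#' @examples
#' evaluate_condition(bistability_condition(), toy_hill_model(),
#'                    c(k_d = 1, k_p = 1, K = 0.5))
#' @export
evaluate_condition <- function(spec, model, params, n_starts = 50,
                               n_grid = 10000) {
  stopifnot(inherits(spec, "hfm_condition"))
  for (cl in spec$clauses) {
    ss <- tryCatch(
      find_steady_states(model, params, cl$input, n_starts = n_starts,
                         n_grid = n_grid),
      error = function(e) {
        warning("root finding failed for condition '", spec$name, "': ",
                conditionMessage(e))
        NULL
      })
    if (is.null(ss)) return(0L)
    lab <- vapply(ss, `[[`, character(1), "stability")
    if (any(lab == "marginal")) return(0L)
    if (sum(lab == "stable") != cl$n_stable ||
        sum(lab == "unstable") != cl$n_unstable) return(0L)
    if (length(cl$thresholds)) {
      stable <- ss[lab == "stable"]
      for (th in cl$thresholds) {
        if (!th$state %in% model$state_names)
          stop("threshold references unknown state: ", th$state)
        vals <- vapply(stable, function(s) s$state[[th$state]], numeric(1))
        v <- if (th$branch == "lower") min(vals) else max(vals)
        ok <- if (th$cmp == "<=") v <= th$value else v >= th$value
        if (!ok) return(0L)
      }
    }
  }
  1L
}

#' Sweep the input and tabulate steady-state branches
#'
#' Produces the data behind a bifurcation diagram: one row per steady state
#' per input level, with the state coordinates and stability label.
#'
#' @inheritParams find_steady_states
#' @param inputs numeric vector of input levels to sweep.
#' @return data frame with columns `input`, `branch`, one column per state,
#'   and `stability`.
#' @export
bifurcation_diagram <- function(model, params, inputs, n_starts = 50,
                                n_grid = 10000) {
  rows <- lapply(inputs, function(u) {
    ss <- find_steady_states(model, params, u, n_starts = n_starts,
                             n_grid = n_grid)
    if (!length(ss)) return(NULL)
    df <- as.data.frame(ss)
    df$max_re_eigenvalue <- NULL
    cbind(input = u, branch = seq_len(nrow(df)), df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
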