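test_that("toy model at the reference parameters has the saddle-node structure", {
  counts <- list(`0` = c(2, 1), `0.2` = c(2, 1), `0.3` = c(1, 0),
                 `1` = c(1, 0))
  for (ks in names(counts)) {
    for (method in c("bracket", "newton")) {
      ss <- find_steady_states(toy, theta_answer, as.numeric(ks),
                               method = method)
      lab <- vapply(ss, `[[`, character(1), "stability")
      expect_equal(sum(lab == "stable"), counts[[ks]][1],
                   info = paste("ks =", ks, method))
      expect_equal(sum(lab == "unstable"), counts[[ks]][2],
                   info = paste("ks =", ks, method))
    }
  }
  # known unstable threshold state at zero input
  ss0 <- find_steady_states(toy, theta_answer, 0)
  expect_equal(ss0[[2]]$state[["Y"]], 0.5, tolerance = 1e-9)
})

test_that("fixture model roots and eigenvalues match the analytic solution", {
  ss <- find_steady_states(fixture, c(alpha = 3, beta = 1), 0, n_starts = 15)
  v <- vapply(ss, function(s) s$state[["v"]], numeric(1))
  expect_equal(v, sort(c(0, (3 - sqrt(5)) / 2, (3 + sqrt(5)) / 2)),
               tolerance = 1e-8)
  expect_equal(vapply(ss, `[[`, character(1), "stability"),
               c("stable", "unstable", "stable"))
  # the origin's Jacobian is lower triangular with diagonal (-1, -1)
  cs <- classify_stability(fixture, c(alpha = 3, beta = 1), 0, c(0, 0))
  expect_equal(sort(Re(cs$eigenvalues)), c(-1, -1))
  expect_equal(cs$stability, "stable")
})

test_that("stability classification matches analytic Jacobians for the toy model", {
  # linear case: unique root k_s/k_d with scalar Jacobian -k_d
  lin <- c(k_d = 2, k_p = 0, K = 0.5)
  cs <- classify_stability(toy, lin, 1, 0.5)
  expect_equal(Re(cs$eigenvalues), -2)
  expect_equal(cs$stability, "stable")
  # threshold state y = K at zero input: derivative -1 + 5/4 * k_p/K ... = 1.5
  cs2 <- classify_stability(toy, theta_answer, 0, 0.5)
  expect_equal(Re(cs2$eigenvalues), 1.5, tolerance = 1e-12)
  expect_equal(cs2$stability, "unstable")
})

test_that("qualitative conditions evaluate to their indicators", {
  expect_identical(evaluate_condition(bistability_condition(), toy,
                                      theta_answer), 1L)
  expect_identical(evaluate_condition(irreversibility_condition(), toy,
                                      theta_answer), 1L)
  # weak feedback cannot sustain bistability
  weak <- c(k_d = 1, k_p = 0.1, K = 0.5)
  expect_identical(evaluate_condition(bistability_condition(), toy, weak), 0L)
})

test_that("output thresholds select the right stable branch", {
  ab <- c(alpha = 3, beta = 1)
  lo_ok <- condition_spec("T1", list(clause(0, 2, 1, list(
    state_threshold("v", "lower", "<=", 1.0)))))
  expect_identical(evaluate_condition(lo_ok, fixture, ab, n_starts = 15), 1L)
  hi_ok <- condition_spec("T2", list(clause(0, 2, 1, list(
    state_threshold("v", "higher", ">=", 2.0)))))
  expect_identical(evaluate_condition(hi_ok, fixture, ab, n_starts = 15), 1L)
  lo_bad <- condition_spec("T3", list(clause(0, 2, 1, list(
    state_threshold("u", "lower", ">=", 1.0)))))
  expect_identical(evaluate_condition(lo_bad, fixture, ab, n_starts = 15), 0L)
  unknown <- condition_spec("T4", list(clause(0, 2, 1, list(
    state_threshold("nope", "lower", "<=", 1.0)))))
  expect_error(evaluate_condition(unknown, fixture, ab, n_starts = 15),
               "unknown state")
})

test_that("finder agrees with an independent bracketing oracle across the prior box", {
  set.seed(42)
  prior <- param_vector(theta_answer)
  for (i in 1:200) {
    th <- prior$lower + runif(3) * (prior$upper - prior$lower)
    pars <- setNames(10^th, prior$names)
    for (ks in c(0, 0.2, 0.3, 1.0)) {
      ss <- find_steady_states(toy, pars, ks)
      hi <- (ks + pars[["k_p"]]) / pars[["k_d"]] + 1
      oracle <- bracket_oracle(function(y) toy_rhs(y, pars, ks), 0, hi)
      expect_equal(length(ss), length(oracle),
                   info = sprintf("i=%d ks=%g", i, ks))
      # generic saddle-node structure: odd count, alternating stability
      lab <- vapply(ss, `[[`, character(1), "stability")
      expect_true(length(ss) %in% c(1, 3))
      if (length(ss) == 3 && !any(lab == "marginal"))
        expect_equal(lab, c("stable", "unstable", "stable"))
    }
  }
})

test_that("bifurcation diagram sweeps branches with their stability", {
  df <- bifurcation_diagram(toy, theta_answer, c(0, 0.1, 0.2, 0.3, 0.5, 1.0))
  expect_named(df, c("input", "branch", "Y", "stability"))
  expect_equal(sum(df$input == 0.2), 3)
  expect_equal(sum(df$input == 1.0), 1)
  # upper stable branch rises with input
  top <- df[df$stability == "stable" & df$Y > 0.8, ]
  expect_true(all(diff(top$Y[order(top$input)]) > 0))
})

test_that("an empty root list is returned when no start converges", {
  # rhs strictly positive on the box: no steady state at all
  ss <- find_steady_states(toy, c(k_d = 1e-4, k_p = 1, K = 0.5), 1,
                           search_box = rbind(lo = 0, hi = 2))
  expect_length(ss, 0)
})
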