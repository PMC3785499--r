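test_that("proposals perturb exactly one coordinate, uniformly chosen", {
  set.seed(10)
  cur <- param_vector(theta_answer)
  picked <- integer(1e5)
  for (i in 1:200) {
    p <- propose(cur, sigma_q = 0.5)
    moved <- which(p$params$log10 != cur$log10)
    expect_lte(length(moved), 1)          # r = 0.5 gives a zero shift
    if (length(moved)) expect_equal(unname(moved), p$index)
    expect_lte(abs(p$params$log10[p$index] - cur$log10[p$index]), 0.5)
  }
  picked <- vapply(seq_len(1e5), function(i) propose(cur)$index, integer(1))
  freq <- tabulate(picked, 3) / 1e5
  expect_true(all(abs(freq - 1 / 3) < 0.01))
})

test_that("both proposal kinds are symmetric in their jumps", {
  set.seed(21)
  cur <- param_vector(c(a = 1))
  for (kind in c("uniform", "normal")) {
    d <- vapply(seq_len(2e4), function(i)
      propose(cur, 0.5, kind)$params$log10[[1]] - cur$log10[[1]], numeric(1))
    br <- seq(0, max(abs(d)) + 1e-9, length.out = 11)
    pos <- hist(d[d > 0], breaks = br, plot = FALSE)$counts
    neg <- hist(-d[d < 0], breaks = br, plot = FALSE)$counts
    keep <- pos + neg > 5
    p <- chisq.test(rbind(pos[keep], neg[keep]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("acceptance probability is the weight ratio capped at one", {
  expect_equal(acceptance_probability(2, 2), 1)
  expect_equal(acceptance_probability(1, 2), 0.5)
  expect_equal(acceptance_probability(0, 2), 0)
  expect_equal(acceptance_probability(5, 1), 1)
  expect_error(acceptance_probability(1, 0), "invariant")
})

test_that("target weight short-circuits on prior box and qualitative failure", {
  prior <- param_vector(theta_answer)
  conds <- list(bistability_condition(), irreversibility_condition())
  w_ref <- target_weight(prior, toy, conds)
  expect_gt(w_ref$weight, 0)
  expect_equal(unname(w_ref$qualitative), c(1L, 1L))

  weak <- set_log10_values(prior, c(0, -1, log10(0.5)))  # k_p at its bound
  w0 <- target_weight(weak, toy, conds)
  expect_equal(w0$weight, 0)
  expect_equal(unname(w0$qualitative[["B"]]), 0L)

  outside <- set_log10_values(prior, c(2, 0, log10(0.5)))
  wo <- target_weight(outside, toy, conds)
  expect_equal(wo$weight, 0)
  expect_true(all(is.na(wo$qualitative)))  # nothing was evaluated

  # observable falling outside every histogram bin zeroes the weight
  far <- histogram_fitness(obs_execution_time("Y"), c(90, 95, 100), c(1, 1))
  wf <- target_weight(prior, toy, conds, list(far), sim = list(input = 1))
  expect_equal(wf$weight, 0)
  expect_equal(unname(wf$quantitative), 0)
})

test_that("a flat target samples the prior box uniformly", {
  prior <- param_vector(theta_answer)
  fit <- mcmc_hfm(NULL, prior = prior,
                  config = mcmc_config(n_steps = 1.1e6, burn_in = 1e5,
                                       thin = 10, seed = 31))
  expect_equal(nrow(fit$samples), 1e5)
  for (p in colnames(fit$samples)) {
    u <- (fit$samples[, p] - prior$lower[[p]]) /
      (prior$upper[[p]] - prior$lower[[p]])
    ks <- suppressWarnings(ks.test(u, "punif"))
    expect_lt(unname(ks$statistic), 0.01)
  }
})

test_that("chain length bookkeeping matches burn-in and thinning", {
  fit <- shared_toy_fit()
  cfg <- fit$config
  expect_equal(nrow(fit$samples),
               floor((cfg$n_steps - cfg$burn_in) / cfg$thin))
  expect_true(all(fit$accept <= fit$propose))
  expect_equal(sum(fit$propose), cfg$n_steps)
})

test_that("every retained sample lies in the box and satisfies all conditions", {
  fit <- shared_toy_fit()
  prior <- fit$prior
  expect_true(all(t(fit$samples) >= prior$lower & t(fit$samples) <= prior$upper))
  set.seed(8)
  idx <- sample(nrow(fit$samples), ceiling(0.01 * nrow(fit$samples)))
  for (i in idx) {
    th <- set_log10_values(prior, fit$samples[i, ])
    for (cond in fit$conditions)
      expect_identical(evaluate_condition(cond, toy, th,
                                          n_grid = fit$config$steady_grid), 1L)
  }
})

test_that("cached chain weights reproduce exactly under recomputation", {
  fit <- shared_toy_fit()
  set.seed(9)
  idx <- sample(nrow(fit$samples), 100)
  for (i in idx) {
    w <- target_weight(set_log10_values(fit$prior, fit$samples[i, ]),
                       toy, fit$conditions, fit$fitness,
                       sim = list(input = 1),
                       steady_grid = fit$config$steady_grid)$weight
    expect_identical(w, fit$weights[i])
  }
})

test_that("the stationary distribution converges to the tabulated target", {
  # 1-parameter problem with explicit per-bin weights: the empirical law
  # must approach weight/sum(weight), with TV distance decreasing in length
  prior <- param_vector(c(x = 1))  # box [-1, 1] on log10 scale
  edges <- seq(-1, 1, length.out = 101)
  mids <- (edges[-1] + edges[-101]) / 2
  w <- 0.15 + dnorm(mids, -0.4, 0.12) + 0.6 * dnorm(mids, 0.5, 0.2)
  f <- histogram_fitness(obs_parameter("x", "log10"), edges, w)
  target <- w / sum(w)
  tv <- vapply(c(1e4, 1e5), function(n) {
    fit <- mcmc_hfm(NULL, fitness = list(f), prior = prior,
                    config = mcmc_config(n_steps = n, burn_in = n / 10,
                                         thin = 1, seed = 13))
    emp <- tabulate(findInterval(fit$samples[, 1], edges,
                                 rightmost.closed = TRUE), 100) /
      nrow(fit$samples)
    0.5 * sum(abs(emp - target))
  }, numeric(1))
  expect_lt(tv[2], tv[1])
  expect_lt(tv[2], 0.05)
})

test_that("the R engine enforces the same invariants on a user model", {
  lin_model <- ode_model(
    key = "lin2", state_names = "x", input_name = "u", param_names = "k",
    rhs = function(y, pars, input) input - pars[["k"]] * y,
    reference = c(k = 1),
    default_box = function(pars, input) rbind(lo = 0, hi = input / pars[["k"]] + 1))
  cond <- condition_spec("one", list(clause(1, 1, 0)))
  fit <- mcmc_hfm(lin_model, list(cond), prior = param_vector(c(k = 1)),
                  config = mcmc_config(n_steps = 400, burn_in = 100, thin = 3,
                                       seed = 7, steady_grid = 200))
  expect_equal(fit$engine, "r")
  expect_equal(nrow(fit$samples), 100)
  expect_true(all(fit$samples >= -1 & fit$samples <= 1))
  expect_true(all(fit$weights == 1))  # indicator-only target
})

test_that("initialization falls back to rejection sampling and can fail", {
  prior <- param_vector(theta_answer)
  conds <- list(bistability_condition())
  # reference start works even when init = "random" draws instead
  fit <- mcmc_hfm(toy, conds, prior = prior,
                  config = mcmc_config(n_steps = 300, burn_in = 50, thin = 1,
                                       seed = 2, init = "random"))
  expect_gt(nrow(fit$samples), 0)
  # an explicit zero-weight start is rejected outright
  expect_error(
    mcmc_hfm(NULL, prior = prior,
             config = mcmc_config(n_steps = 100, burn_in = 10,
                                  init = c(k_d = 9, k_p = 0, K = 0))),
    "zero target weight|initial")
})
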