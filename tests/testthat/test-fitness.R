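test_that("threshold observables match linear-model closed forms", {
  lin <- c(k_d = 1, k_p = 0, K = 0.5)
  tr <- integrate_rk4(toy, lin, input = 1, t_end = 100, dt = 0.01)
  # y(t) = 1 - exp(-t): 90% of max crossed at about ln 10
  expect_lt(abs(execution_time(tr, "Y") - log(10)), 0.0101)
  # 2.5% -> 97.5% crossing gap is ln 39
  expect_lt(abs(switching_time(tr, "Y") - log(39)), 0.0101)
  expect_equal(endpoint_value(tr, "Y", 100), 1, tolerance = 1e-9)
  expect_error(endpoint_value(tr, "Y", 200), "beyond")

  # doubling the rate halves the switching time
  tr2 <- integrate_rk4(toy, c(k_d = 2, k_p = 0, K = 0.5), input = 2,
                       t_end = 50, dt = 0.01)
  expect_lt(abs(switching_time(tr2, "Y") - log(39) / 2), 0.0101)
})

test_that("constant trajectories report time zero", {
  tr <- integrate_rk4(toy, c(k_d = 1, k_p = 0, K = 0.5), input = 0, t_end = 5)
  expect_equal(execution_time(tr, "Y"), 0)
  expect_equal(switching_time(tr, "Y"), 0)
  tr$states[, 1] <- 2  # constant nonzero level
  expect_equal(execution_time(tr, "Y"), 0)
})

test_that("crossing times are monotone in the threshold fraction", {
  tr <- integrate_rk4(toy, theta_answer, input = 1, t_end = 100)
  fr <- seq(0.05, 0.95, by = 0.05)
  te <- vapply(fr, function(f) execution_time(tr, "Y", f), numeric(1))
  expect_true(all(diff(te) >= 0))
})

test_that("endpoint is consistent with the stable branch from bifurcation analysis", {
  tr <- integrate_rk4(toy, theta_answer, input = 1, t_end = 100)
  ss <- find_steady_states(toy, theta_answer, 1)
  expect_equal(endpoint_value(tr, "Y", 100), ss[[1]]$state[["Y"]],
               tolerance = 1e-3)
})

test_that("histogram fitness follows the half-open binning convention", {
  h <- histogram_fitness(obs_execution_time("Y"), bin_edges = c(0, 1, 2, 3),
                         frequencies = c(10, 120, 7))
  expect_equal(eval_fitness(h, 1.5), 120)
  expect_equal(eval_fitness(h, -0.5), 0)   # below the first edge
  expect_equal(eval_fitness(h, 3.5), 0)    # above the last edge
  expect_equal(eval_fitness(h, 1), 120)    # interior edge goes right
  expect_equal(eval_fitness(h, 0), 10)
  expect_equal(eval_fitness(h, 3), 7)      # last bin closed on the right
  expect_error(histogram_fitness(obs_execution_time("Y"), c(0, 1), c(-1)),
               "non-negative")
  expect_error(histogram_fitness(obs_execution_time("Y"), c(0, 1, 0.5),
                                 c(1, 1)), "increasing")
})

test_that("log-normal moment inversion is exact and round-trips by simulation", {
  # frozen from the closed-form inversion, cross-checked by simulation below
  ms <- lognormal_from_moments(23, 10)
  expect_lt(abs(ms[["mu"]] - 3.048923), 1e-5)
  expect_lt(abs(ms[["sigma"]] - 0.416104), 1e-5)
  ms2 <- lognormal_from_moments(15, 3)
  expect_lt(abs(ms2[["mu"]] - 2.688440), 1e-5)
  expect_lt(abs(ms2[["sigma"]] - 0.198042), 1e-5)
  # degenerate limit
  ms3 <- lognormal_from_moments(7, 1e-8)
  expect_equal(ms3[["mu"]], log(7), tolerance = 1e-9)
  expect_error(lognormal_from_moments(-1, 1), "positive")

  set.seed(1)
  for (m in list(c(23, 10), c(15, 3))) {
    p <- lognormal_from_moments(m[1], m[2])
    z <- rlnorm(1e6, p[["mu"]], p[["sigma"]])
    expect_equal(mean(z), m[1], tolerance = 0.01)
    expect_equal(sd(z), m[2], tolerance = 0.01)
  }
})

test_that("log-normal fitness is a normalized density with the closed-form mode", {
  f <- lognormal_fitness(obs_switching_time("Y"), mean = 23, sd = 10)
  expect_equal(eval_fitness(f, -1), 0)
  expect_equal(eval_fitness(f, 0), 0)
  total <- integrate(function(z) sapply(z, eval_fitness, f = f), 0, 500)$value
  expect_equal(total, 1, tolerance = 1e-4)
  grid <- seq(1, 60, by = 0.01)
  dens <- sapply(grid, eval_fitness, f = f)
  expect_equal(grid[which.max(dens)], exp(f$mu - f$sigma^2), tolerance = 0.01)
})

test_that("fitness evaluations are bounded and non-negative", {
  h <- histogram_fitness(obs_endpoint("Y", 100), seq(0, 5, by = 0.5),
                         frequencies = rpois(10, 40) + 1)
  z <- runif(500, -1, 6)
  v <- sapply(z, eval_fitness, f = h)
  expect_true(all(v >= 0))
  expect_true(all(v <= max(h$frequencies)))
})

test_that("histogram fitness round-trips through CSV plus sidecar", {
  h <- histogram_fitness(obs_execution_time("Y", 0.9), c(0, 1, 2), c(3, 4))
  path <- file.path(tempdir(), "hist.csv")
  write_histogram_fitness(h, path)
  h2 <- read_histogram_fitness(path)
  expect_equal(h2$bin_edges, h$bin_edges)
  expect_equal(h2$frequencies, h$frequencies)
  expect_equal(h2$observable$kind, "execution_time")
  expect_equal(h2$observable$code, 0L)
})
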