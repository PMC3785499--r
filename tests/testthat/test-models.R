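test_that("toy model right-hand side matches hand-computed values", {
  # at y = 0 the degradation and Hill terms vanish
  expect_equal(toy_rhs(0, theta_answer, k_s = 1.0), 1.0)
  # at y = K the Hill term is k_p/2: 1 - 0.5 + 0.5
  expect_equal(toy_rhs(0.5, theta_answer, k_s = 1.0), 1.0)
  # y = 0.5 solves y^5 - y^4 + K^5 = 0 for K = 0.5, so the rhs vanishes
  expect_equal(toy_rhs(0.5, theta_answer, k_s = 0.0), 0.0)
  expect_error(toy_rhs(-0.1, theta_answer, k_s = 1.0), "negative")
  expect_error(toy_rhs(0.5, c(k_d = 1, k_p = 1), k_s = 1.0), "missing")
})

test_that("fixture model right-hand side has the analytic fixed points", {
  ab <- c(alpha = 3, beta = 1)
  expect_equal(fixture_rhs(c(0, 0), ab, input = 0), c(0, 0))
  vstar <- (3 + sqrt(5)) / 2  # nonzero root of v(v^2 - 3v + 1) = 0
  expect_equal(fixture_rhs(c(vstar, vstar), ab, input = 0), c(0, 0),
               tolerance = 1e-12)
  expect_equal(fixture_rhs(c(1, 0), ab, input = 0), c(-1, 1))
})

test_that("RK4 reproduces the linear-model closed form and its order", {
  lin <- c(k_d = 1, k_p = 0, K = 0.5)  # feedback disabled
  tr <- integrate_rk4(toy, lin, input = 1, t_end = 10, dt = 0.01)
  expect_equal(endpoint_value(tr, "Y", 10), 1 - exp(-10), tolerance = 1e-9)

  # max error against the closed form scales as dt^p with p >= 3.5
  errs <- vapply(c(0.04, 0.02, 0.01), function(dt) {
    tr <- integrate_rk4(toy, lin, input = 1, t_end = 10, dt = dt)
    max(abs(tr$states[, "Y"] - linear_solution(tr$times)))
  }, numeric(1))
  p <- coef(lm(log(errs) ~ log(c(0.04, 0.02, 0.01))))[[2]]
  expect_gte(p, 3.5)
})

test_that("degenerate inputs give the expected trajectories", {
  tr <- integrate_rk4(toy, c(k_d = 1, k_p = 0, K = 0.5), input = 0, t_end = 5)
  expect_true(all(tr$states == 0))
  expect_error(integrate_rk4(toy, theta_answer, 1, t_end = 0.005, dt = 0.01),
               "multiple")
  expect_error(integrate_rk4(toy, theta_answer, 1, y0 = NA), "finite")
})

test_that("reference dynamics saturate early at full input", {
  tr <- integrate_rk4(toy, theta_answer, input = 1.0, t_end = 100)
  y <- tr$states[, "Y"]
  expect_gte(y[tr$times == 10], 0.9 * y[length(y)])
})

test_that("noisy simulation is seeded, clamped, and exact in the zero-noise limit", {
  base <- integrate_rk4(toy, theta_answer, 1.0, t_end = 20)
  nz0 <- simulate_noisy(toy, theta_answer, 1.0, t_end = 20,
                        noise_variance = 0, seed = 5)
  expect_identical(nz0$states, base$states)

  a <- simulate_noisy(toy, theta_answer, 1.0, t_end = 20, noise_variance = 1,
                      seed = 11)
  b <- simulate_noisy(toy, theta_answer, 1.0, t_end = 20, noise_variance = 1,
                      seed = 11)
  expect_identical(a$states, b$states)
  expect_true(all(a$states >= 0))
  expect_gt(max(abs(a$states - base$states)), 0)  # noise actually applied
  expect_equal(a$noise$variance, 1)
})

test_that("user-registered models integrate through the R fallback", {
  lin_model <- ode_model(
    key = "lin1", state_names = "x", input_name = "u", param_names = "k",
    rhs = function(y, pars, input) input - pars[["k"]] * y,
    reference = c(k = 1),
    default_box = function(pars, input) rbind(lo = 0, hi = input / pars[["k"]] + 1))
  tr <- integrate_rk4(lin_model, c(k = 1), input = 1, t_end = 10, dt = 0.01)
  ref <- integrate_rk4(toy, c(k_d = 1, k_p = 0, K = 0.5), input = 1,
                       t_end = 10, dt = 0.01)
  expect_equal(tr$states[, "x"], ref$states[, "Y"], tolerance = 1e-12)

  set.seed(3)
  nz <- simulate_noisy(lin_model, c(k = 1), 1, t_end = 2, noise_variance = 0.5)
  expect_true(all(nz$states >= 0))
})

test_that("trajectories export as CSV with a JSON sidecar", {
  tr <- simulate_noisy(toy, theta_answer, 1.0, t_end = 1, noise_variance = 0.1,
                       seed = 4)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  df <- read.csv(path)
  expect_identical(names(df), c("time", "Y"))
  expect_equal(nrow(df), 101)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$noise$variance, 0.1)
  expect_equal(meta$noise$seed, 4)
})
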