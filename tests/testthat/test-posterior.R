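test_that("credible intervals match order statistics of known samples", {
  set.seed(2)
  u <- runif(1e6)
  x <- matrix(log10(u), ncol = 1, dimnames = list(NULL, "x"))
  m <- marginal_summary(x, "x", range = c(-8, 0))
  expect_equal(m$ci[["lower"]], 0.025, tolerance = 0.005 / 0.025)
  expect_equal(m$ci[["upper"]], 0.975, tolerance = 0.005 / 0.975)
  expect_equal(sum(m$probabilities), 1, tolerance = 1e-12)
})

test_that("point-mass and box-spanning traces give the degenerate summaries", {
  x <- matrix(rep(0.25, 1000), ncol = 1, dimnames = list(NULL, "x"))
  m <- marginal_summary(x, "x", range = c(-1, 1))
  expect_equal(m$log10_width, 0)
  expect_lt(abs(m$mode_log10 - 0.25), 0.0201)  # mode is the bin centre
  # a trace sitting on the box edges spans the full two-decade prior
  x2 <- matrix(rep(c(-1, 1), 500), ncol = 1, dimnames = list(NULL, "x"))
  m2 <- marginal_summary(x2, "x", range = c(-1, 1))
  expect_equal(m2$log10_width, 2.0)
})

test_that("correlation matrix handles exact and degenerate dependence", {
  set.seed(3)
  a <- runif(1e4)
  x <- cbind(a = a, b = a, c = -a)
  r <- correlation_matrix(x)
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  big <- cbind(a = runif(1e6), b = runif(1e6))
  expect_lt(abs(correlation_matrix(big)["a", "b"]), 0.005)
  expect_warning(correlation_matrix(cbind(a = rep(1, 10), b = 1:10)),
                 "zero-variance")
})

test_that("joint histograms are consistent with the marginals", {
  fit <- shared_toy_fit()
  j <- joint_histogram(fit, "k_d", "K", n_bins = 50)
  expect_equal(sum(j$probabilities), 1, tolerance = 1e-12)
  expect_equal(rowSums(j$probabilities),
               marginal_summary(fit, "k_d")$probabilities, tolerance = 1e-12)
  expect_equal(colSums(j$probabilities),
               marginal_summary(fit, "K")$probabilities, tolerance = 1e-12)
})

test_that("a single-point trace yields a point-mass predictive histogram", {
  fit <- shared_toy_fit()
  fit$samples <- matrix(rep(log10(theta_answer), each = 50), nrow = 50,
                        dimnames = list(NULL, names(theta_answer)))
  h <- observable_histogram(fit, obs_execution_time("Y"), n_bins = 20)
  expect_equal(sum(h$frequencies > 0), 1)
  tr <- integrate_rk4(toy, theta_answer, 1, t_end = 100)
  te <- execution_time(tr, "Y")
  bin <- findInterval(te, h$bin_edges, rightmost.closed = TRUE)
  expect_gt(h$frequencies[bin], 0)
})

test_that("posterior-predictive histograms overlap the generating histograms", {
  fit <- shared_toy_fit()
  gen <- shared_toy_hists()$Te
  pred <- observable_histogram(fit, obs_execution_time("Y"), subsample = 2000,
                               breaks = gen$bin_edges)
  p_pred <- pred$frequencies / sum(pred$frequencies)
  # more than half the predicted mass falls in bins the data histogram occupies
  expect_gt(sum(p_pred[gen$frequencies > 0]), 0.5)
})

test_that("predictive histograms are stable under sub-sampling rate changes", {
  fit <- shared_toy_fit()
  gen <- shared_toy_hists()$Te
  set.seed(4)
  h1 <- observable_histogram(fit, obs_execution_time("Y"),
                             subsample = floor(nrow(fit$samples) * 0.1),
                             breaks = gen$bin_edges)
  h2 <- observable_histogram(fit, obs_execution_time("Y"),
                             subsample = nrow(fit$samples),
                             breaks = gen$bin_edges)
  p1 <- h1$frequencies / sum(h1$frequencies)
  p2 <- h2$frequencies / sum(h2$frequencies)
  expect_lt(max(abs(p1 - p2)), 0.02)
})

test_that("fit methods expose modes, intervals and samples coherently", {
  fit <- shared_toy_fit()
  s <- summary(fit)
  expect_named(coef(fit), c("k_d", "k_p", "K"))
  expect_equal(unname(coef(fit)), s$table$mode)
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), s$table$ci_lower)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_identical(as.matrix(fit), fit$samples)
  # mode bin is stable under further thinning by two (up to one bin)
  half <- fit
  half$samples <- fit$samples[seq(1, nrow(fit$samples), by = 2), , drop = FALSE]
  for (p in colnames(fit$samples)) {
    bw <- (fit$prior$upper[[p]] - fit$prior$lower[[p]]) / 50
    expect_lte(abs(marginal_summary(fit, p)$mode_log10 -
                     marginal_summary(half, p)$mode_log10), bw + 1e-12)
  }
})
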