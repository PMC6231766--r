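test_that("empirical CDF is a right-continuous step function", {
  e <- interval_ecdf(c(1, 2, 2, 4))
  expect_equal(ecdf_eval(e, 2), 0.75)
  expect_equal(ecdf_eval(e, 4), 1.0)
  expect_equal(ecdf_eval(e, 0.5), 0)
  expect_equal(ecdf_eval(e, 1.999), 0.25)
  expect_true(all(diff(e$values) >= 0))
  expect_error(interval_ecdf(numeric(0)), "empty")
  expect_error(interval_ecdf(c(1, -2)), "positive")
})

test_that("hyperexponential fit recovers simulated mixture parameters", {
  # estimates average over replicates to the generating parameters; a single
  # n = 5000 sample carries sampling error comparable to the tolerance
  mp <- mini_interval_params(w_fast = 0.64, tau_fast_ms = 170,
                             tau_slow_ms = 740)
  est <- vapply(1:5, function(s) {
    times <- simulate_mini_times(mp, 375.2 * 5500, seed = 30 + s)
    fit <- fit_hyperexponential(diff(times)[1:5000])
    expect_lt(fit$tau_fast_ms, fit$tau_slow_ms)
    expect_equal(fit$percent_fast, 100 * fit$w_fast)
    c(fit$w_fast, fit$tau_fast_ms, fit$tau_slow_ms)
  }, numeric(3))
  expect_lt(abs(mean(est[1, ]) - 0.64), 0.05)
  expect_lt(abs(mean(est[2, ]) / 170 - 1), 0.10)
  expect_lt(abs(mean(est[3, ]) / 740 - 1), 0.10)
})

test_that("fitted mixture CDF is a valid distribution function", {
  times <- simulate_mini_times(mini_interval_params(), 375.2 * 600, seed = 13)
  fit <- fit_hyperexponential(diff(times))
  tg <- seq(0, 5000, by = 10)
  Fv <- hyperexp_cdf(tg, fit$w_fast, fit$tau_fast_ms, fit$tau_slow_ms)
  expect_equal(Fv[1], 0)
  expect_true(all(diff(Fv) >= 0))
  expect_gt(tail(Fv, 1), 0.99)
})

test_that("degenerate single-exponential data collapses the mixture", {
  set.seed(7)
  iv <- rexp(3000, 1 / 200)
  fit <- fit_hyperexponential(iv)
  # either nearly all weight on one component or both taus nearly equal
  collapsed <- fit$w_fast >= 0.95 || fit$w_fast <= 0.05 ||
    abs(fit$tau_fast_ms / fit$tau_slow_ms - 1) < 0.10
  expect_true(collapsed)
  expect_error(fit_hyperexponential(iv[1:10]), "50")
})

test_that("KS2 statistic equals the maximum vertical ECDF difference", {
  expect_equal(ks2(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks2(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks2(c(1, 2, 3, 4), c(2, 3, 4, 5))$D, 0.25)
  # brute force over pooled points on random small-sample pairs
  set.seed(50)
  for (i in 1:200) {
    a <- runif(sample(3:12, 1), 0, 10)
    b <- runif(sample(3:12, 1), 0, 10)
    k <- ks2(a, b)
    expect_equal(k$D, ks_brute(a, b))
    expect_equal(k$D, ks2(b, a)$D)  # symmetry
  }
})

test_that("KS2 D and p agree with the reference implementation", {
  set.seed(60)
  a <- rexp(80, 1 / 200)
  b <- rexp(120, 1 / 300)
  ours <- ks2(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(ours$D, unname(ref$statistic))
  expect_lt(abs(ours$p_value - ref$p.value), 0.01)
})

test_that("CDF difference curve is consistent with the KS statistic", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  ea <- interval_ecdf(a); eb <- interval_ecdf(b)
  grid <- sort(unique(c(a, b)))
  d <- cdf_difference(ea, eb, grid)
  expect_true(all(abs(d$difference) <= 1))
  expect_equal(max(abs(d$difference)), ks2(a, b)$D)
  expect_equal(cdf_difference(ea, ea, grid)$difference, rep(0, length(grid)))
  # stochastic dominance: shifting right cannot lower the difference
  eb2 <- interval_ecdf(a + 2)
  expect_true(all(cdf_difference(ea, eb2, grid)$difference >= 0))
})

test_that("Grubbs screening flags gross outliers iteratively", {
  res <- grubbs(c(rep(1, 9), 10), alpha = 0.01)
  expect_equal(res$outlier_indices, 10L)
  # G = 2.846 for this configuration; critical ~2.48 at n = 10, alpha = 0.01
  expect_equal(res$G, 2.846, tolerance = 1e-3)
  expect_equal(grubbs(c(1, 1.1, 0.9))$outlier_indices, integer(0))
  expect_equal(grubbs(rep(2, 8))$outlier_indices, integer(0))
  # iterative removal: two clear outliers among many
  res2 <- grubbs(c(rnorm(20, 0, 0.01) + 1, 50, 80), alpha = 0.01)
  expect_setequal(res2$outlier_indices, c(21L, 22L))
  expect_error(grubbs(c(1, 2)), "n >= 3")
})
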