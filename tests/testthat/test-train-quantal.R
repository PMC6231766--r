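test_that("paired-pulse ratio is P2/P1 and matches the model closed form", {
  expect_equal(paired_pulse_ratio(epsc_train(c(6.85, 4.93), 5)), 0.72,
               tolerance = 1e-3)
  expect_equal(paired_pulse_ratio(epsc_train(c(3, 3), 5)), 1)
  # deterministic model: PPR = 1 - p + r*ipi/N0
  tr <- simulate_train_deterministic(pool_ctrl(), proto_100hz())
  expect_equal(paired_pulse_ratio(tr), 1 - 0.44 + 0.622 / 16.3,
               tolerance = 1e-12)
  expect_error(paired_pulse_ratio(epsc_train(c(0, 1), 5)), "P1")
  expect_error(paired_pulse_ratio(epsc_train(5, 5)), ">= 2")
})

test_that("cumulative EPSC sums follow the geometric closed form", {
  expect_equal(cumulative_epsc(epsc_train(c(5, 2.5, 1.25), 10)),
               c(5, 7.5, 8.75))
  expect_equal(cumulative_epsc(epsc_train(c(0, 0), 10)), c(0, 0))
  # depletion-only: C_n = N0 * (1 - (1-p)^n)
  pool <- release_pool_params(N0_nA = 8, p = 0.35)
  tr <- simulate_train_deterministic(pool, stim_protocol(25, 10))
  expect_equal(tail(cumulative_epsc(tr), 1), 8 * (1 - 0.65^25),
               tolerance = 1e-12)
})

test_that("cumulative-EPSC regression recovers RRP, Pr1 and replenishment", {
  # depletion-only: pool fully depleted inside the window, slope ~ 0
  tr <- simulate_train_deterministic(release_pool_params(10, 0.5),
                                     stim_protocol(30, 10))
  est <- estimate_quantal_train(tr)
  expect_equal(est$rrp_nA, 10, tolerance = 1e-4)
  expect_equal(est$pr1, 0.5, tolerance = 1e-4)
  expect_lt(abs(est$slope_pA_per_ms), 1e-3)

  # with replenishment: intercept N0 - r*ipi/p, slope r (residual depletion
  # transient at stimulus 20 is (1-p)^20 ~ 1e-5, bounding the agreement)
  est2 <- estimate_quantal_train(
    simulate_train_deterministic(pool_ctrl(), proto_100hz()))
  expect_equal(est2$rrp_nA, 16.3 - 0.622 / 0.44, tolerance = 1e-4)
  expect_equal(est2$slope_pA_per_ms, 62.2, tolerance = 1e-4)
  expect_equal(est2$pr1, simulate_train_deterministic(
    pool_ctrl(), proto_100hz())$amplitudes_nA[1] / est2$rrp_nA)
  expect_length(est2$flags, 0)

  # Methods-style alternative window gives the same answer at steady state
  est3 <- estimate_quantal_train(
    simulate_train_deterministic(pool_ctrl(), proto_100hz()),
    window = c(15, 30))
  expect_equal(est3$rrp_nA, est2$rrp_nA, tolerance = 1e-3)
  expect_error(estimate_quantal_train(tr, window = c(20, 40)), "shorter")
})

test_that("cumulative regression is exact across a (p, r) grid", {
  # a window deep enough that the depletion transient (1-p)^k is below
  # machine-level for every p in the grid
  for (p in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
    for (r in c(0, 10, 25, 40, 62.2)) {
      if (r * 10 / 1000 > 0.1 * 16 * p) next  # premise: E1 well above r*ipi
      pool <- release_pool_params(16, p, r)
      est <- estimate_quantal_train(
        simulate_train_deterministic(pool, proto_100hz(200)),
        window = c(150, 200))
      expect_lt(abs(est$slope_pA_per_ms - r), 1e-9)
      expect_lt(abs(est$rrp_nA - (16 - r * 10 / 1000 / p)), 1e-6 * 16)
    }
  }
})

test_that("RRP is frequency invariant up to the predicted r*ipi/p offset", {
  est100 <- estimate_quantal_train(
    simulate_train_deterministic(pool_ctrl(), stim_protocol(30, 10)))
  est200 <- estimate_quantal_train(
    simulate_train_deterministic(pool_ctrl(), stim_protocol(30, 5)))
  predicted_offset <- (62.2 * 10 - 62.2 * 5) / 1000 / 0.44
  expect_equal(est200$rrp_nA - est100$rrp_nA, predicted_offset,
               tolerance = 1e-3)
})

test_that("exponential-decay method recovers p exactly on clean trains", {
  for (p in seq(0.1, 0.9, by = 0.1)) {
    tr <- simulate_train_deterministic(release_pool_params(12, p),
                                       stim_protocol(30, 10))
    ef <- estimate_pr_exponential(tr)
    expect_lt(abs(ef$pr - p), 1e-6)
    expect_equal(ef$fc, 1)
    expect_equal(ef$rrp_nA, 12, tolerance = 1e-5)
  }
  # replenishment only shifts the fitted offset, not the decay constant
  ef2 <- estimate_pr_exponential(
    simulate_train_deterministic(pool_ctrl(), proto_100hz()))
  expect_lt(abs(ef2$pr - 0.44), 1e-6)
})

test_that("facilitation correction divides Pr by RP0/R0", {
  tr <- simulate_train_deterministic(release_pool_params(10, 0.3),
                                     stim_protocol(30, 10))
  amps <- tr$amplitudes_nA
  amps[1] <- amps[1] * 0.8  # first pulse 20% below the fitted curve
  ef <- estimate_pr_exponential(epsc_train(amps, 10))
  expect_equal(ef$fc, 1.25, tolerance = 1e-3)
  expect_equal(ef$pr, 0.3 / 1.25, tolerance = 1e-3)
})

test_that("stochastic trains recover the deterministic oracle on average", {
  # binomial release, q = 50 pA, cv = 0.3, at calyx-scale parameters
  ests <- vapply(1:200, function(s) {
    tr <- simulate_train_stochastic(pool_ctrl(), proto_100hz(), seed = s)
    est <- estimate_quantal_train(tr)
    c(est$rrp_nA, est$slope_pA_per_ms, est$pr1)
  }, numeric(3))
  oracle <- estimate_quantal_train(
    simulate_train_deterministic(pool_ctrl(), proto_100hz()))
  expect_lt(abs(mean(ests[1, ]) / oracle$rrp_nA - 1), 0.10)
  expect_lt(abs(mean(ests[2, ]) / oracle$slope_pA_per_ms - 1), 0.10)
  expect_lt(abs(mean(ests[3, ]) / oracle$pr1 - 1), 0.10)
})

test_that("train normalization and treatment ratios behave elementwise", {
  expect_equal(normalize_train(epsc_train(c(4, 2, 1), 10)), c(1, 0.5, 0.25))
  expect_equal(normalize_train(epsc_train(c(3, 3, 3), 10)), c(1, 1, 1))
  tr <- simulate_train_deterministic(release_pool_params(9, 0.4),
                                     stim_protocol(10, 10))
  expect_equal(normalize_train(tr), 0.6^(0:9), tolerance = 1e-12)

  expect_equal(treatment_ratio(c(2, 2), c(2, 2)), c(1, 1))
  expect_equal(treatment_ratio(1.4 * c(5, 3), c(5, 3)), c(1.4, 1.4))
  expect_error(treatment_ratio(c(1, 2), c(1, 2, 3)), "length")
  expect_error(treatment_ratio(c(1, 2), c(1, 0)), "> 0")
  # steady-state ratio of two deterministic models = ratio of r*ipi
  aniso <- release_pool_params(16.3, 0.29, 96.9)
  ctrl <- pool_ctrl()
  ta <- simulate_train_deterministic(aniso, proto_100hz(100))$amplitudes_nA
  tc <- simulate_train_deterministic(ctrl, proto_100hz(100))$amplitudes_nA
  expect_equal(tail(treatment_ratio(ta, tc), 1), 96.9 / 62.2,
               tolerance = 1e-6)
})

test_that("replenishment fold changes reproduce the reported rounding", {
  expect_equal(replenishment_fold_change(102.8, 62.2)$fold_2dp, 1.65)
  expect_equal(replenishment_fold_change(154.1, 96.9)$fold_2dp, 1.59)
  expect_equal(replenishment_fold_change(5, 5)$fold, 1)
  expect_error(replenishment_fold_change(5, 0), "> 0")
})

test_that("group summaries average per-cell estimates", {
  g <- group_mean_sem(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$sem, sd(1:3) / sqrt(3))
  expect_equal(g$n, 3)
})
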