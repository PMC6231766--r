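test_that("detector recovers noise-free rendered events", {
  tr <- render_trace(c(100, 300, 500), 40, mini_kernel(), duration_ms = 700,
                     noise_sd_pA = 0)
  ev <- detect_minis(tr)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$amplitude_pA - 40) < 1))
  # peak occurs one kernel-peak latency after the event onset time
  expect_true(all(abs(ev$peak_time_ms - c(100, 300, 500)) < 1))
  expect_true(all(diff(ev$peak_time_ms) > 0))
})

test_that("sub-threshold and empty traces yield no events", {
  tr8 <- render_trace(200, 8, mini_kernel(), duration_ms = 500,
                      noise_sd_pA = 0)
  expect_equal(nrow(detect_minis(tr8)), 0)

  flat <- structure(list(fs_hz = 20000, samples = rep(0, 20000), t0_ms = 0),
                    class = "trace")
  expect_equal(nrow(detect_minis(flat)), 0)
  expect_error(detect_minis(structure(list(fs_hz = 20000,
                                           samples = numeric(0), t0_ms = 0),
                                      class = "trace")), "empty")
})

test_that("detection has perfect recall and precision on a clean suite", {
  # 100 events >= 20 pA, separated by >= 50 ms, no noise
  set.seed(100)
  times <- seq(100, by = 60, length.out = 100) + runif(100, 0, 9)
  amps <- runif(100, 20, 60)
  tr <- render_trace(times, amps, mini_kernel(),
                     duration_ms = max(times) + 100, noise_sd_pA = 0)
  ev <- detect_minis(tr)
  expect_equal(nrow(ev), 100)  # precision: no spurious events
  matched <- vapply(times, function(t) any(abs(ev$peak_time_ms - t) < 2),
                    logical(1))
  expect_true(all(matched))    # recall: every true event found
  ord <- order(times)
  expect_true(all(abs(ev$amplitude_pA - amps[ord]) < 1))
})

test_that("detected amplitudes are invariant to a constant offset", {
  tr <- render_trace(c(100, 200), 30, mini_kernel(), duration_ms = 400,
                     noise_sd_pA = 0)
  shifted <- tr
  shifted$samples <- tr$samples - 120
  ev0 <- detect_minis(tr)
  ev1 <- detect_minis(shifted)
  expect_equal(ev1$amplitude_pA, ev0$amplitude_pA, tolerance = 1e-6)
  expect_equal(ev1$peak_time_ms, ev0$peak_time_ms)
})

test_that("events survive concatenation with a silent gap", {
  tr <- render_trace(c(100, 200), 30, mini_kernel(), duration_ms = 300,
                     noise_sd_pA = 0)
  gap <- rep(0, 20000)  # 1 s of silence, longer than every window
  joined <- structure(list(fs_hz = 20000,
                           samples = c(tr$samples, gap, tr$samples),
                           t0_ms = 0),
                      class = "trace")
  ev <- detect_minis(joined)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$amplitude_pA[3:4], ev$amplitude_pA[1:2], tolerance = 1e-6)
})

test_that("shape statistics match the kernel's analytic rise and decay", {
  k <- mini_kernel(0.2, 1.5)
  tr <- render_trace(50, 40, k, duration_ms = 200, noise_sd_pA = 0)
  ev <- detect_minis(tr)
  # analytic 10-90% rise and half-decay of the unit-peak kernel on a fine grid
  tg <- seq(0, 30, by = 1e-4)
  kv <- eval_kernel(k, tg)
  ipk <- which.max(kv)
  rise_ref <- tg[min(which(kv >= 0.9))] - tg[min(which(kv >= 0.1))]
  half_ref <- tg[ipk - 1 + min(which(kv[ipk:length(kv)] <= 0.5))] - tg[ipk]
  expect_equal(ev$rise_10_90_ms, rise_ref, tolerance = 0.06)
  expect_equal(ev$decay_half_ms, half_ref, tolerance = 0.06)
})

test_that("event summaries report frequency and flagged means", {
  ev <- data.frame(peak_time_ms = seq(0, 29000, length.out = 60),
                   amplitude_pA = rep(40, 60), rise_10_90_ms = 0.4,
                   decay_half_ms = 1, decay_10_90_ms = 2, area_pA_ms = 50)
  s <- event_summary(ev, 30000)
  expect_equal(s$frequency_hz, 2.0)
  s72 <- event_summary(ev[rep(1, 72), ], 30000)
  expect_equal(s72$frequency_hz, 2.4)
  s0 <- event_summary(empty <- detect_minis(render_trace(
    numeric(0), numeric(0), mini_kernel(), duration_ms = 1000)), 1000)
  expect_equal(s0$frequency_hz, 0)
  expect_true(is.na(s0$amplitude_pA[["mean"]]))
})
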