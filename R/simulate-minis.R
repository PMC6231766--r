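#' Hyperexponential interval CDF
#'
#' Closed-form CDF of the two-component exponential mixture used to model
#' inter-event intervals of spontaneous release:
#' `F(t) = 1 - [w * exp(-t/tau_f) + (1 - w) * exp(-t/tau_s)]`.
#'
#' @param t_ms Times (ms).
#' @param w_fast Weight of the fast component.
#' @param tau_fast_ms,tau_slow_ms Component means (ms).
#' @return CDF values in `[0, 1]`.
#' @export
hyperexp_cdf <- function(t_ms, w_fast, tau_fast_ms, tau_slow_ms) {
  ifelse(t_ms < 0, 0,
         1 - (w_fast * exp(-t_ms / tau_fast_ms) +
                (1 - w_fast) * exp(-t_ms / tau_slow_ms)))
}

#' Simulate spontaneous event times
#'
#' Generates event times of a renewal process whose inter-event intervals are
#' hyperexponential: each interval is exponential with mean `tau_fast_ms`
#' (probability `w_fast`) or `tau_slow_ms` (otherwise). Times are strictly
#' increasing within `[0, duration_ms]`; an empty vector is returned when the
#' first interval exceeds the duration.
#'
#' @param params A [mini_interval_params()].
#' @param duration_ms Recording duration (ms, > 0).
#' @param seed Mandatory RNG seed.
#' @return Numeric vector of event times (ms), possibly empty.
#' @export
simulate_mini_times <- function(params, duration_ms, seed) {
  stopifnot(inherits(params, "mini_interval_params"))
  stop_if_not_scalar_number(duration_ms, "duration_ms")
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  with_seed_required(seed, {
    # draw in blocks until the cumulative time passes the duration
    mean_iv <- params$w_fast * params$tau_fast_ms +
      (1 - params$w_fast) * params$tau_slow_ms
    times <- numeric(0)
    t_last <- 0
    repeat {
      n_draw <- max(16L, ceiling(1.5 * (duration_ms - t_last) / mean_iv))
      fast <- runif(n_draw) < params$w_fast
      iv <- ifelse(fast, rexp(n_draw, 1 / params$tau_fast_ms),
                   rexp(n_draw, 1 / params$tau_slow_ms))
      new_t <- t_last + cumsum(iv)
      times <- c(times, new_t)
      t_last <- tail(new_t, 1)
      if (t_last > duration_ms) break
    }
    times[times <= duration_ms]
  })
}

#' Render a current trace from event times
#'
#' Builds a signed current trace (pA) at sampling rate `fs_hz` by placing a
#' unit-peak biexponential kernel at each event time, scaled by the event
#' amplitude, with inward (negative) polarity, plus optional Gaussian noise.
#' With zero noise the trough of an isolated event equals minus its amplitude
#' to within the kernel-peak quantization of one sample.
#'
#' @param times_ms Event times (ms), within the trace duration.
#' @param amplitudes_pA Positive event magnitudes (pA), recycled if scalar.
#' @param kernel A [mini_kernel()].
#' @param duration_ms Trace duration (ms).
#' @param noise_sd_pA Gaussian noise SD (pA, >= 0).
#' @param fs_hz Sampling rate (Hz, default 20000).
#' @param seed RNG seed; required only when `noise_sd_pA > 0`.
#' @return A `trace` object: list with `fs_hz`, `samples` (pA, signed),
#'   `t0_ms`.
#' @export
render_trace <- function(times_ms, amplitudes_pA, kernel = mini_kernel(),
                         duration_ms, noise_sd_pA = 0, fs_hz = 20000,
                         seed = NULL) {
  stopifnot(inherits(kernel, "mini_kernel"))
  stop_if_not_scalar_number(fs_hz, "fs_hz")
  if (fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  stop_if_not_scalar_number(duration_ms, "duration_ms")
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  if (length(times_ms) > 0 &&
      (any(times_ms < 0) || any(times_ms > duration_ms))) {
    stop("event times must lie within [0, duration_ms]", call. = FALSE)
  }
  if (length(times_ms) > 0) {
    amplitudes_pA <- rep_len(amplitudes_pA, length(times_ms))
    if (any(amplitudes_pA < 0)) {
      stop("amplitudes are positive magnitudes", call. = FALSE)
    }
  }
  n <- ceiling(duration_ms * fs_hz / 1000) + 1L
  dt_ms <- 1000 / fs_hz
  samples <- numeric(n)
  # kernel support: ~8 decay constants
  support_n <- ceiling((kernel$t_peak_ms + 8 * kernel$tau_decay_ms) / dt_ms)
  for (i in seq_along(times_ms)) {
    i0 <- floor(times_ms[i] / dt_ms) + 1L
    idx <- i0:min(n, i0 + support_n)
    t_rel <- (idx - 1L) * dt_ms - times_ms[i]
    samples[idx] <- samples[idx] - amplitudes_pA[i] * eval_kernel(kernel, t_rel)
  }
  if (noise_sd_pA > 0) {
    samples <- samples + with_seed_required(seed, rnorm(n, 0, noise_sd_pA))
  }
  structure(list(fs_hz = fs_hz, samples = samples, t0_ms = 0),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("current trace: %d samples at %g Hz (%.4g s), range [%.4g, %.4g] pA\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Simulate a spontaneous-release recording
#'
#' Convenience wrapper combining [simulate_mini_times()] and [render_trace()]:
#' draws event times and Gaussian amplitudes (truncated at 1 pA), renders a
#' signed trace, and returns the ground truth along with it.
#'
#' @inheritParams simulate_mini_times
#' @param kernel A [mini_kernel()].
#' @param noise_sd_pA Trace noise SD (pA).
#' @param fs_hz Sampling rate (Hz).
#' @return List with `trace`, `times_ms`, `amplitudes_pA`.
#' @export
simulate_mini_recording <- function(params, duration_ms, seed,
                                    kernel = mini_kernel(), noise_sd_pA = 2,
                                    fs_hz = 20000) {
  with_seed_required(seed, {
    times <- simulate_mini_times(params, duration_ms, seed = seed + 1L)
    amps <- pmax(1, rnorm(length(times), params$amp_mean_pA, params$amp_sd_pA))
    tr <- render_trace(times, amps, kernel, duration_ms, noise_sd_pA,
                       fs_hz, seed = seed + 2L)
    list(trace = tr, times_ms = times, amplitudes_pA = amps)
  })
}
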