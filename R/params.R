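#' Generative parameters of evoked vesicle release
#'
#' Describes a releasable pool of synaptic vesicles expressed as summed
#' postsynaptic current. A stimulus releases a fraction `p` of the standing
#' pool; between stimuli the pool refills at a constant rate `r_pA_per_ms`
#' and is capped at its initial size `N0_nA`. Optional paired-pulse
#' facilitation transiently increments the release fraction.
#'
#' @param N0_nA Initial releasable pool, as summed postsynaptic current (nA).
#' @param p Per-stimulus release fraction in `[0, 1]`.
#' @param r_pA_per_ms Replenishment rate (pA/ms of response-equivalent).
#' @param q_pA Quantal (single-vesicle) response amplitude (pA); only used by
#'   the stochastic simulator.
#' @param q_cv Coefficient of variation of the quantal amplitude (>= 0).
#' @param facilitation_df Additive increment to the release fraction
#'   contributed by each stimulus; decays between stimuli with `tau_f_ms`.
#'   Defaults to 0 (facilitation off).
#' @param tau_f_ms Decay time constant of facilitation (ms).
#' @return An object of class `release_pool_params`.
#' @examples
#' release_pool_params(N0_nA = 16.3, p = 0.44, r_pA_per_ms = 62.2)
#' @export
release_pool_params <- function(N0_nA, p, r_pA_per_ms = 0, q_pA = 50,
                                q_cv = 0, facilitation_df = 0, tau_f_ms = 50) {
  stop_if_not_scalar_number(N0_nA, "N0_nA")
  stop_if_not_scalar_number(p, "p")
  stop_if_not_scalar_number(r_pA_per_ms, "r_pA_per_ms")
  stop_if_not_scalar_number(q_pA, "q_pA")
  stop_if_not_scalar_number(q_cv, "q_cv")
  stop_if_not_scalar_number(facilitation_df, "facilitation_df")
  stop_if_not_scalar_number(tau_f_ms, "tau_f_ms")
  if (N0_nA <= 0) stop("N0_nA must be > 0", call. = FALSE)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (r_pA_per_ms < 0) stop("r_pA_per_ms must be >= 0", call. = FALSE)
  if (q_pA <= 0) stop("q_pA must be > 0", call. = FALSE)
  if (q_cv < 0) stop("q_cv must be >= 0", call. = FALSE)
  if (facilitation_df < 0) stop("facilitation_df must be >= 0", call. = FALSE)
  if (tau_f_ms <= 0) stop("tau_f_ms must be > 0", call. = FALSE)
  structure(list(N0_nA = N0_nA, p = p, r_pA_per_ms = r_pA_per_ms,
                 q_pA = q_pA, q_cv = q_cv,
                 facilitation_df = facilitation_df, tau_f_ms = tau_f_ms),
            class = "release_pool_params")
}

#' Stimulation protocol for an evoked train
#'
#' @param n_stim Number of stimuli (>= 1).
#' @param ipi_ms Inter-pulse interval (ms, > 0). 10 ms corresponds to 100 Hz
#'   stimulation, 5 ms to 200 Hz.
#' @return An object of class `stim_protocol` with a derived `freq_hz` field.
#' @examples
#' stim_protocol(n_stim = 30, ipi_ms = 10)  # 100 Hz
#' @export
stim_protocol <- function(n_stim, ipi_ms) {
  stop_if_not_scalar_number(n_stim, "n_stim")
  stop_if_not_scalar_number(ipi_ms, "ipi_ms")
  if (n_stim < 1 || n_stim != round(n_stim)) {
    stop("n_stim must be an integer >= 1", call. = FALSE)
  }
  if (ipi_ms <= 0) stop("ipi_ms must be > 0", call. = FALSE)
  structure(list(n_stim = as.integer(n_stim), ipi_ms = ipi_ms,
                 freq_hz = 1000 / ipi_ms),
            class = "stim_protocol")
}

#' Parameters of the spontaneous-event interval distribution
#'
#' Inter-event intervals of spontaneous (miniature EPSC) release are modelled
#' as a two-component exponential mixture (hyperexponential): with probability
#' `w_fast` an interval is drawn from an exponential with mean `tau_fast_ms`,
#' otherwise from one with mean `tau_slow_ms`. Event amplitudes are Gaussian.
#'
#' @param w_fast Mixture weight of the fast component in `[0, 1]`.
#' @param tau_fast_ms,tau_slow_ms Exponential means (ms); fast < slow.
#' @param amp_mean_pA,amp_sd_pA Event amplitude distribution (pA).
#' @return An object of class `mini_interval_params`.
#' @export
mini_interval_params <- function(w_fast = 0.64, tau_fast_ms = 170,
                                 tau_slow_ms = 740, amp_mean_pA = 37,
                                 amp_sd_pA = 8) {
  stop_if_not_scalar_number(w_fast, "w_fast")
  stop_if_not_scalar_number(tau_fast_ms, "tau_fast_ms")
  stop_if_not_scalar_number(tau_slow_ms, "tau_slow_ms")
  stop_if_not_scalar_number(amp_mean_pA, "amp_mean_pA")
  stop_if_not_scalar_number(amp_sd_pA, "amp_sd_pA")
  if (w_fast < 0 || w_fast > 1) stop("w_fast must lie in [0, 1]", call. = FALSE)
  if (tau_fast_ms <= 0) stop("tau_fast_ms must be > 0", call. = FALSE)
  if (tau_fast_ms >= tau_slow_ms) {
    stop("tau_fast_ms must be < tau_slow_ms", call. = FALSE)
  }
  if (amp_mean_pA <= 0) stop("amp_mean_pA must be > 0", call. = FALSE)
  if (amp_sd_pA < 0) stop("amp_sd_pA must be >= 0", call. = FALSE)
  structure(list(w_fast = w_fast, tau_fast_ms = tau_fast_ms,
                 tau_slow_ms = tau_slow_ms, amp_mean_pA = amp_mean_pA,
                 amp_sd_pA = amp_sd_pA),
            class = "mini_interval_params")
}

#' Biexponential miniature-EPSC waveform kernel
#'
#' The kernel `k(t) = c * (exp(-t/tau_decay) - exp(-t/tau_rise))` is
#' normalized so that a unit-amplitude event has unit peak. Defaults give a
#' sub-millisecond rise and a millisecond-scale decay typical of AMPA-receptor
#' mEPSCs at a large auditory brainstem synapse.
#'
#' @param tau_rise_ms,tau_decay_ms Rise/decay time constants (ms); rise < decay.
#' @return An object of class `mini_kernel`.
#' @export
mini_kernel <- function(tau_rise_ms = 0.2, tau_decay_ms = 1.5) {
  stop_if_not_scalar_number(tau_rise_ms, "tau_rise_ms")
  stop_if_not_scalar_number(tau_decay_ms, "tau_decay_ms")
  if (tau_rise_ms <= 0 || tau_decay_ms <= 0 || tau_rise_ms >= tau_decay_ms) {
    stop("require 0 < tau_rise_ms < tau_decay_ms", call. = FALSE)
  }
  # peak of the unnormalized difference-of-exponentials
  t_peak <- tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
  peak <- exp(-t_peak / tau_decay_ms) - exp(-t_peak / tau_rise_ms)
  structure(list(tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 t_peak_ms = t_peak, norm = 1 / peak),
            class = "mini_kernel")
}

#' Evaluate a mini kernel at given times
#'
#' @param kernel A [mini_kernel()].
#' @param t_ms Times in ms (>= 0 contributes; negative times give 0).
#' @return Kernel values, unit peak amplitude.
#' @export
eval_kernel <- function(kernel, t_ms) {
  stopifnot(inherits(kernel, "mini_kernel"))
  v <- numeric(length(t_ms))
  ok <- t_ms >= 0
  v[ok] <- kernel$norm *
    (exp(-t_ms[ok] / kernel$tau_decay_ms) - exp(-t_ms[ok] / kernel$tau_rise_ms))
  v
}

#' Parameters for synthetic two-channel image pairs
#'
#' @param shape Integer vector `c(rows, cols)`, each >= 16.
#' @param r_target Desired Pearson correlation between the two channels,
#'   in `[-1, 1]`.
#' @param signal_mean,signal_sd Intensity mean/sd of the signal component
#'   (arbitrary 0-255 units).
#' @param bg_level Additive background level.
#' @return An object of class `image_sim_params`.
#' @export
image_sim_params <- function(shape = c(256, 256), r_target = 0.78,
                             signal_mean = 100, signal_sd = 30,
                             bg_level = 16) {
  if (!is.numeric(shape) || length(shape) != 2L || any(!is.finite(shape))) {
    stop("shape must be c(rows, cols)", call. = FALSE)
  }
  if (any(shape < 16)) stop("image shape must be at least 16 x 16", call. = FALSE)
  stop_if_not_scalar_number(r_target, "r_target")
  if (abs(r_target) > 1) stop("|r_target| must be <= 1", call. = FALSE)
  stop_if_not_scalar_number(signal_mean, "signal_mean")
  stop_if_not_scalar_number(signal_sd, "signal_sd")
  stop_if_not_scalar_number(bg_level, "bg_level")
  if (signal_sd <= 0) stop("signal_sd must be > 0", call. = FALSE)
  if (bg_level < 0) stop("bg_level must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), r_target = r_target,
                 signal_mean = signal_mean, signal_sd = signal_sd,
                 bg_level = bg_level),
            class = "image_sim_params")
}

#' Miniature-EPSC detection parameters
#'
#' Defaults reproduce a standard mini-detection parameter set used for
#' AMPA-mEPSC analysis: amplitude threshold 10 pA, 20 ms local-maximum search,
#' baseline averaged over 2 ms ending 5 ms before the peak, half-decay search
#' within 5 ms, area threshold 10 pA*ms, 3-point peak averaging, negative
#' (inward) polarity.
#'
#' @param threshold_pA Amplitude threshold (pA).
#' @param peak_search_ms Window after a threshold crossing to search for the
#'   local extremum (ms).
#' @param baseline_lead_ms Time before the peak at which the baseline window
#'   ends (ms).
#' @param baseline_avg_ms Length of the baseline averaging window (ms).
#' @param decay_search_ms Window after the peak to search for the decay
#'   crossing (ms).
#' @param decay_fraction Fraction of the peak at which decay time is read
#'   (in (0, 1)).
#' @param area_threshold_pA_ms Minimum event area (pA*ms).
#' @param peak_avg_points Number of samples averaged for the peak value.
#' @param polarity `"negative"` (inward currents) or `"positive"`.
#' @param baseline_window_ms Length of the trailing running-median window used
#'   to remove slow baseline drift before thresholding (ms).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_pA = 10, peak_search_ms = 20,
                             baseline_lead_ms = 5, baseline_avg_ms = 2,
                             decay_search_ms = 5, decay_fraction = 0.5,
                             area_threshold_pA_ms = 10, peak_avg_points = 3,
                             polarity = c("negative", "positive"),
                             baseline_window_ms = 50) {
  polarity <- match.arg(polarity)
  for (nm in c("threshold_pA", "peak_search_ms", "baseline_lead_ms",
               "baseline_avg_ms", "decay_search_ms", "decay_fraction",
               "area_threshold_pA_ms", "peak_avg_points",
               "baseline_window_ms")) {
    stop_if_not_scalar_number(get(nm), nm)
    if (get(nm) <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  if (decay_fraction >= 1) stop("decay_fraction must be in (0, 1)", call. = FALSE)
  structure(list(threshold_pA = threshold_pA, peak_search_ms = peak_search_ms,
                 baseline_lead_ms = baseline_lead_ms,
                 baseline_avg_ms = baseline_avg_ms,
                 decay_search_ms = decay_search_ms,
                 decay_fraction = decay_fraction,
                 area_threshold_pA_ms = area_threshold_pA_ms,
                 peak_avg_points = as.integer(peak_avg_points),
                 polarity = polarity,
                 baseline_window_ms = baseline_window_ms),
            class = "detection_params")
}
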