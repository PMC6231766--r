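as_train <- function(train) {
  if (inherits(train, "epsc_train")) return(train)
  stop("expected an 'epsc_train' object (see epsc_train())", call. = FALSE)
}

#' Paired-pulse ratio
#'
#' Ratio of the second evoked response to the first, `P2 / P1`. Values below
#' 1 indicate paired-pulse depression, above 1 facilitation.
#'
#' @param train An [epsc_train()] with at least two stimuli and `P1 > 0`.
#' @return The ratio.
#' @examples
#' paired_pulse_ratio(epsc_train(c(6.85, 4.93), ipi_ms = 5))  # ~0.72
#' @export
paired_pulse_ratio <- function(train) {
  train <- as_train(train)
  a <- train$amplitudes_nA
  if (length(a) < 2) stop("paired-pulse ratio needs >= 2 stimuli", call. = FALSE)
  if (a[1] <= 0) stop("P1 must be > 0", call. = FALSE)
  a[2] / a[1]
}

#' Cumulative EPSC amplitude
#'
#' @param train An [epsc_train()].
#' @return Non-decreasing vector `C_k = sum_{i<=k} P_i` (nA).
#' @export
cumulative_epsc <- function(train) {
  cumsum(as_train(train)$amplitudes_nA)
}

#' Estimate RRP, release probability and replenishment from a cumulative
#' EPSC train
#'
#' Back-extrapolation method: a least-squares line is fit through the
#' cumulative EPSC amplitudes `C_k` for stimuli in `window` (where the train
#' has reached steady state). Its y-intercept (evaluated at stimulus 0) is
#' the readily releasable pool (RRP, nA); the slope per stimulus, divided by
#' the inter-pulse interval, is the replenishment rate in pA/ms; and the
#' first-pulse release probability is `Pr1 = P1 / RRP`.
#'
#' @param train An [epsc_train()] covering at least `window[2]` stimuli.
#' @param window Integer pair `(first, last)` of the steady-state fit window
#'   (default `c(20, 30)`; `c(15, 30)` is a common alternative).
#' @return An object of class `train_quantal_estimate`: `rrp_nA`,
#'   `slope_pA_per_ms`, `pr1`, `fit_window`, and `flags` (character vector;
#'   non-empty when the intercept is non-positive or `pr1` falls outside
#'   `[0, 1]`).
#' @export
estimate_quantal_train <- function(train, window = c(20, 30)) {
  train <- as_train(train)
  a <- train$amplitudes_nA
  if (length(window) != 2 || window[1] >= window[2] || window[1] < 1) {
    stop("window must be (first, last) with 1 <= first < last", call. = FALSE)
  }
  if (length(a) < window[2]) {
    stop("train shorter than the fit window", call. = FALSE)
  }
  k <- seq(window[1], window[2])
  C <- cumsum(a)[k]
  fit <- lm(C ~ k)
  rrp <- unname(coef(fit)[1])
  slope_per_stim_nA <- unname(coef(fit)[2])
  slope_pA_per_ms <- slope_per_stim_nA * 1000 / train$ipi_ms
  pr1 <- a[1] / rrp
  flags <- character(0)
  if (rrp <= 0) flags <- c(flags, "non-positive RRP intercept")
  if (!is.finite(pr1) || pr1 < 0 || pr1 > 1) {
    flags <- c(flags, "pr1 outside [0, 1]")
  }
  structure(list(rrp_nA = rrp, slope_pA_per_ms = slope_pA_per_ms, pr1 = pr1,
                 fit_window = window, ipi_ms = train$ipi_ms, flags = flags),
            class = "train_quantal_estimate")
}

#' @export
print.train_quantal_estimate <- function(x, ...) {
  cat(sprintf(
    "cumulative-EPSC estimate (window %d-%d): RRP = %.4g nA, Pr1 = %.3g, replenishment = %.4g pA/ms\n",
    x$fit_window[1], x$fit_window[2], x$rrp_nA, x$pr1, x$slope_pA_per_ms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Estimate release probability by exponential decay of the train
#'
#' Fits a single exponential `P_k = P_ss + A * exp(-(k - 1)/tau)` to the
#' peak amplitudes against stimulus number (profiled least squares: for each
#' candidate `tau` the linear coefficients are solved exactly, and `tau` is
#' optimized in one dimension). The fit uses stimuli 2 onward and is
#' extrapolated back to stimulus 1, so that a facilitated (depressed-looking)
#' first response cannot drag the fitted curve toward itself. The release
#' probability follows from the decay constant as `Pr = 1 - exp(-1/tau)`.
#' When the observed first response `R0` is smaller than the fitted curve's
#' value at stimulus 1 (`RP0`), a facilitation correction `Fc = RP0 / R0 > 1`
#' is applied and `Pr` is divided by it; otherwise `Fc = 1`. The implied pool
#' size is `RRP = RP0 / Pr`.
#'
#' @param train An [epsc_train()] with at least 10 stimuli.
#' @param tau_range Search interval for `tau` (stimulus units).
#' @return An object of class `exp_fit_estimate`: `tau_stim`, `pr`, `fc`,
#'   `rp0_nA` (fitted value at stimulus 1), `r0_nA` (observed first
#'   response), `rrp_nA`, `p_ss_nA`, `rss`.
#' @export
estimate_pr_exponential <- function(train, tau_range = c(0.05, 500)) {
  train <- as_train(train)
  P <- train$amplitudes_nA
  n <- length(P)
  if (n < 10) stop("exponential fit needs >= 10 stimuli", call. = FALSE)
  k <- 2:n
  Pk <- P[k]

  rss_tau <- function(tau) {
    x <- exp(-(k - 1) / tau)
    f <- lm.fit(cbind(1, x), Pk)
    sum(f$residuals^2)
  }
  opt <- optimize(rss_tau, interval = tau_range, tol = 1e-10)
  tau <- opt$minimum
  if (!is.finite(tau) || tau <= 0) {
    stop("exponential fit failed: non-positive tau", call. = FALSE)
  }
  x <- exp(-(k - 1) / tau)
  cf <- lm.fit(cbind(1, x), Pk)$coefficients
  p_ss <- unname(cf[1]); A <- unname(cf[2])
  if (A <= 0) {
    stop("exponential fit failed: train does not decay", call. = FALSE)
  }
  rp0 <- p_ss + A           # fitted curve at stimulus 1
  r0 <- P[1]
  fc <- if (r0 < rp0) rp0 / r0 else 1
  pr <- (1 - exp(-1 / tau)) / fc
  structure(list(tau_stim = tau, pr = pr, fc = fc, rp0_nA = rp0, r0_nA = r0,
                 rrp_nA = rp0 / pr, p_ss_nA = p_ss, rss = opt$objective),
            class = "exp_fit_estimate")
}

#' @export
print.exp_fit_estimate <- function(x, ...) {
  cat(sprintf(
    "exponential-decay estimate: tau = %.4g stimuli, Pr = %.3g (Fc = %.3g), RRP = %.4g nA\n",
    x$tau_stim, x$pr, x$fc, x$rrp_nA))
  invisible(x)
}

#' Normalize a train to its first response
#'
#' @param train An [epsc_train()] with `P1 > 0`.
#' @return Vector `P_k / P1`; first element 1.
#' @export
normalize_train <- function(train) {
  train <- as_train(train)
  a <- train$amplitudes_nA
  if (a[1] <= 0) stop("P1 must be > 0 for normalization", call. = FALSE)
  a / a[1]
}

#' Per-stimulus treated/control response ratio
#'
#' Elementwise ratio of non-normalized mean peak amplitudes, treated over
#' control, used to show sustained differences during prolonged stimulation.
#'
#' @param mean_treated,mean_control Equal-length numeric vectors (nA);
#'   control entries must be > 0.
#' @return Ratio vector.
#' @export
treatment_ratio <- function(mean_treated, mean_control) {
  if (length(mean_treated) != length(mean_control)) {
    stop("treated and control vectors must have equal length", call. = FALSE)
  }
  if (any(mean_control <= 0)) {
    stop("control entries must be > 0", call. = FALSE)
  }
  mean_treated / mean_control
}

#' Fold change of replenishment rate between stimulation frequencies
#'
#' @param rate_hi_pA_per_ms Replenishment rate at the higher frequency.
#' @param rate_lo_pA_per_ms Replenishment rate at the lower frequency (> 0).
#' @return List with `fold` (raw) and `fold_2dp` (rounded to 2 decimals, as
#'   reported).
#' @examples
#' replenishment_fold_change(102.8, 62.2)$fold_2dp  # 1.65
#' @export
replenishment_fold_change <- function(rate_hi_pA_per_ms, rate_lo_pA_per_ms) {
  stop_if_not_scalar_number(rate_hi_pA_per_ms, "rate_hi_pA_per_ms")
  stop_if_not_scalar_number(rate_lo_pA_per_ms, "rate_lo_pA_per_ms")
  if (rate_lo_pA_per_ms <= 0) stop("rate_lo must be > 0", call. = FALSE)
  fold <- rate_hi_pA_per_ms / rate_lo_pA_per_ms
  list(fold = fold, fold_2dp = round(fold, 2))
}

#' Group summary of per-cell estimates
#'
#' Averages per-cell quantal estimates the way group statistics are reported:
#' each cell contributes one estimate, and the group value is mean +/- SEM of
#' the per-cell values (not the estimate from group-mean traces).
#'
#' @param values Numeric vector of per-cell estimates.
#' @return List with `mean`, `sem`, `n`.
#' @export
group_mean_sem <- function(values) {
  v <- values[is.finite(values)]
  list(mean = mean(v),
       sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
       n = length(v))
}
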