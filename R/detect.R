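#' Detect miniature EPSCs in a current trace
#'
#' Threshold-based event detection in the style of classical mini-analysis
#' tools. The trace is first flattened by subtracting a trailing running
#' median (window `baseline_window_ms`), removing slow drift so that the
#' amplitude threshold is applied baseline-relative. Candidate events are
#' threshold crossings in the requested polarity; for each crossing the
#' extremum within `peak_search_ms` is taken (peak value averaged over
#' `peak_avg_points` samples), a local baseline is measured as the mean over
#' `baseline_avg_ms` ending `baseline_lead_ms` before the peak, and the event
#' amplitude is the baseline-to-peak difference. The 10-90% rise time, the
#' time from the peak back to `decay_fraction` of the amplitude (searched
#' within `decay_search_ms`), the 90-10% decay time, and the event area
#' (integral of the baseline-subtracted signal over the event window, pA*ms)
#' are computed per event. Events below the amplitude or area thresholds are
#' rejected; candidate peaks closer than one search window keep only the
#' larger extremum.
#'
#' @param trace A `trace` object (see [render_trace()]) or numeric vector of
#'   samples in pA (then `fs_hz` is taken from `params_fs_hz`).
#' @param params A [detection_params()].
#' @param params_fs_hz Sampling rate used when `trace` is a bare numeric
#'   vector.
#' @return A data.frame with one row per event: `peak_time_ms`,
#'   `amplitude_pA` (positive magnitude), `rise_10_90_ms`, `decay_half_ms`,
#'   `decay_10_90_ms`, `area_pA_ms`, sorted by peak time.
#' @export
detect_minis <- function(trace, params = detection_params(),
                         params_fs_hz = 20000) {
  stopifnot(inherits(params, "detection_params"))
  if (inherits(trace, "trace")) {
    x <- trace$samples
    fs <- trace$fs_hz
  } else if (is.numeric(trace)) {
    x <- as.numeric(trace)
    fs <- params_fs_hz
  } else {
    stop("trace must be a 'trace' object or numeric vector", call. = FALSE)
  }
  if (length(x) == 0) stop("empty trace", call. = FALSE)
  dt_ms <- 1000 / fs
  min_len <- ceiling(max(params$peak_search_ms,
                         params$baseline_lead_ms + params$baseline_avg_ms,
                         params$decay_search_ms) / dt_ms)
  if (length(x) <= min_len) {
    stop("trace shorter than the detection windows", call. = FALSE)
  }

  # trailing running-median baseline; runmed is centered, so shift by half a
  # window to make it trailing
  k <- floor(params$baseline_window_ms / dt_ms)
  if (k %% 2 == 0) k <- k + 1L
  k <- max(3L, min(k, length(x) - (1 - length(x) %% 2)))
  bl <- as.numeric(runmed(x, k, endrule = "median"))
  half <- (k - 1L) %/% 2L
  bl <- c(rep(bl[1], half), head(bl, length(x) - half))
  # z: baseline-relative deflection, positive in the event direction
  sgn <- if (params$polarity == "negative") -1 else 1
  z <- sgn * (x - bl)

  search_n <- max(1L, round(params$peak_search_ms / dt_ms))
  peak_half <- (params$peak_avg_points - 1L) %/% 2L

  # rising-edge threshold crossings
  above <- z >= params$threshold_pA
  starts <- which(above & !c(FALSE, head(above, -1)))
  if (length(starts) == 0) return(empty_events())

  peaks <- integer(0)
  i <- 1L
  while (i <= length(starts)) {
    s <- starts[i]
    win_end <- min(length(x), s + search_n)
    pk <- s - 1L + which.max(z[s:win_end])
    peaks <- c(peaks, pk)
    # skip crossings swallowed by this search window
    i <- i + 1L
    while (i <= length(starts) && starts[i] <= win_end) i <- i + 1L
  }
  # merge peaks closer than one search window: keep the larger extremum
  if (length(peaks) > 1) {
    keep <- rep(TRUE, length(peaks))
    for (j in 2:length(peaks)) {
      prev <- max(which(keep[1:(j - 1)]))
      if (peaks[j] - peaks[prev] <= search_n) {
        if (z[peaks[j]] > z[peaks[prev]]) keep[prev] <- FALSE else keep[j] <- FALSE
      }
    }
    peaks <- peaks[keep]
  }

  bl_n <- max(1L, round(params$baseline_avg_ms / dt_ms))
  lead_n <- round(params$baseline_lead_ms / dt_ms)
  decay_n <- max(1L, round(params$decay_search_ms / dt_ms))

  out <- lapply(peaks, function(pk) {
    # local baseline from the raw trace
    b_end <- pk - lead_n
    b_start <- max(1L, b_end - bl_n + 1L)
    if (b_end < 1L) { b_start <- 1L; b_end <- 1L }
    base <- mean(x[b_start:b_end])
    pk_lo <- max(1L, pk - peak_half)
    pk_hi <- min(length(x), pk + peak_half)
    peak_val <- mean(x[pk_lo:pk_hi])
    amp <- sgn * (peak_val - base)
    if (!is.finite(amp) || amp < params$threshold_pA) return(NULL)

    y <- sgn * (x - base)  # baseline-subtracted, event-positive

    # 10-90% rise by linear interpolation on the rising limb
    rise <- cross_time_before(y, pk, 0.1 * amp, 0.9 * amp, dt_ms)
    onset_idx <- rise$onset_idx

    # half-decay: first return to decay_fraction * amp within decay_search
    d_end <- min(length(x), pk + decay_n)
    decay_half <- cross_time_after(y, pk, d_end, params$decay_fraction * amp,
                                   dt_ms)
    decay_10_90 <- {
      t90 <- cross_time_after(y, pk, d_end, 0.9 * amp, dt_ms)
      t10 <- cross_time_after(y, pk, d_end, 0.1 * amp, dt_ms)
      if (is.na(t90) || is.na(t10)) NA_real_ else t10 - t90
    }

    # area over the event window: onset to return-to-10% (or search end)
    a_end_t <- cross_time_after(y, pk, d_end, 0.1 * amp, dt_ms)
    a_end <- if (is.na(a_end_t)) d_end else min(length(x),
                                                pk + ceiling(a_end_t / dt_ms))
    a_start <- max(1L, onset_idx)
    area <- sum(y[a_start:a_end]) * dt_ms
    if (!is.finite(area) || area < params$area_threshold_pA_ms) return(NULL)

    data.frame(peak_time_ms = (pk - 1L) * dt_ms,
               amplitude_pA = amp,
               rise_10_90_ms = rise$rise_ms,
               decay_half_ms = decay_half,
               decay_10_90_ms = decay_10_90,
               area_pA_ms = area)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_events())
  ev <- do.call(rbind, out)
  ev[order(ev$peak_time_ms), , drop = FALSE]
}

empty_events <- function() {
  data.frame(peak_time_ms = numeric(0), amplitude_pA = numeric(0),
             rise_10_90_ms = numeric(0), decay_half_ms = numeric(0),
             decay_10_90_ms = numeric(0), area_pA_ms = numeric(0))
}

# 10->90% rise time on the rising limb ending at the peak; returns the rise
# time and the onset (10%) sample index
cross_time_before <- function(y, pk, lo, hi, dt_ms) {
  i <- pk
  t_hi <- NA_real_; t_lo <- NA_real_; onset_idx <- pk
  while (i > 1L) {
    if (is.na(t_hi) && y[i - 1L] < hi && y[i] >= hi) {
      frac <- (hi - y[i - 1L]) / (y[i] - y[i - 1L])
      t_hi <- (i - 2L + frac) * dt_ms
    }
    if (y[i - 1L] < lo && y[i] >= lo) {
      frac <- (lo - y[i - 1L]) / (y[i] - y[i - 1L])
      t_lo <- (i - 2L + frac) * dt_ms
      onset_idx <- i - 1L
      break
    }
    i <- i - 1L
  }
  rise <- if (is.na(t_hi) || is.na(t_lo)) NA_real_ else t_hi - t_lo
  list(rise_ms = rise, onset_idx = onset_idx)
}

# first downward crossing of `level` after the peak, as time-from-peak (ms)
cross_time_after <- function(y, pk, end, level, dt_ms) {
  if (end <= pk) return(NA_real_)
  seg <- y[pk:end]
  below <- which(seg <= level)
  below <- below[below > 1L]
  if (length(below) == 0) return(NA_real_)
  j <- below[1]
  frac <- (seg[j - 1L] - level) / (seg[j - 1L] - seg[j])
  (j - 2L + frac) * dt_ms
}

#' Summarize detected miniature events
#'
#' @param events Event data.frame from [detect_minis()].
#' @param duration_ms Recording duration (ms, > 0).
#' @return List with `n_events`, `frequency_hz` (= count / duration in s),
#'   and mean +/- SEM of amplitude, rise, half-decay, 10-90% decay and area.
#'   With no events the frequency is 0 and the shape statistics are `NA`.
#' @examples
#' ev <- data.frame(peak_time_ms = seq(0, 29500, length.out = 60),
#'                  amplitude_pA = 40, rise_10_90_ms = 0.4,
#'                  decay_half_ms = 1, decay_10_90_ms = 2, area_pA_ms = 50)
#' event_summary(ev, 30000)$frequency_hz  # 2 Hz
#' @export
event_summary <- function(events, duration_ms) {
  stop_if_not_scalar_number(duration_ms, "duration_ms")
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  n <- nrow(events)
  mstat <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) return(c(mean = NA_real_, sem = NA_real_))
    c(mean = mean(v),
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }
  list(n_events = n,
       duration_ms = duration_ms,
       frequency_hz = n / (duration_ms / 1000),
       amplitude_pA = mstat(events$amplitude_pA),
       rise_10_90_ms = mstat(events$rise_10_90_ms),
       decay_half_ms = mstat(events$decay_half_ms),
       decay_10_90_ms = mstat(events$decay_10_90_ms),
       area_pA_ms = mstat(events$area_pA_ms))
}
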