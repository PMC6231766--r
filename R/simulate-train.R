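#' Construct an evoked EPSC train
#'
#' Container for ordered per-stimulus peak amplitudes. Amplitudes are
#' positive magnitudes in nA; the inter-pulse interval fixes the stimulation
#' frequency (1000/ipi_ms Hz).
#'
#' @param amplitudes_nA Numeric vector of peak magnitudes (nA, >= 0).
#' @param ipi_ms Inter-pulse interval (ms, > 0).
#' @return An object of class `epsc_train`.
#' @export
epsc_train <- function(amplitudes_nA, ipi_ms) {
  if (!is.numeric(amplitudes_nA) || length(amplitudes_nA) < 1L ||
      any(!is.finite(amplitudes_nA))) {
    stop("amplitudes_nA must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(amplitudes_nA < 0)) {
    stop("amplitudes are positive magnitudes; negative values not allowed",
         call. = FALSE)
  }
  stop_if_not_scalar_number(ipi_ms, "ipi_ms")
  if (ipi_ms <= 0) stop("ipi_ms must be > 0", call. = FALSE)
  structure(list(amplitudes_nA = as.numeric(amplitudes_nA), ipi_ms = ipi_ms),
            class = "epsc_train")
}

#' @export
print.epsc_train <- function(x, ...) {
  cat(sprintf("EPSC train: %d stimuli at %.4g Hz (ipi %.4g ms)\n",
              length(x$amplitudes_nA), 1000 / x$ipi_ms, x$ipi_ms))
  cat(sprintf("  P1 = %.4g nA, steady state (last) = %.4g nA\n",
              x$amplitudes_nA[1], tail(x$amplitudes_nA, 1)))
  invisible(x)
}

#' @export
length.epsc_train <- function(x) length(x$amplitudes_nA)

# per-stimulus release fraction trajectory with optional decaying facilitation
p_trajectory <- function(pool, protocol) {
  p_k <- numeric(protocol$n_stim)
  f <- 0
  decay <- exp(-protocol$ipi_ms / pool$tau_f_ms)
  for (k in seq_len(protocol$n_stim)) {
    p_k[k] <- min(1, pool$p + f)
    f <- (f + pool$facilitation_df) * decay
  }
  p_k
}

#' Simulate a deterministic evoked EPSC train
#'
#' Mean-field depletion-replenishment model. At stimulus `k` the response is
#' `E_k = p_k * N_k`; between stimuli the pool refills by `r * ipi`
#' (converted to nA) and is capped at `N0`:
#' `N_{k+1} = min(N0, N_k - E_k + r * ipi)`. With facilitation off the
#' amplitudes decay monotonically to the fixed point `r * ipi` whenever
#' `E_1 > r * ipi`. The quantal size plays no role in deterministic mode.
#'
#' @param pool A [release_pool_params()].
#' @param protocol A [stim_protocol()].
#' @return An [epsc_train()] of `n_stim` amplitudes (nA).
#' @examples
#' pool <- release_pool_params(N0_nA = 10, p = 0.5)
#' simulate_train_deterministic(pool, stim_protocol(4, 10))$amplitudes_nA
#' # 5.0 2.5 1.25 0.625 : pure geometric depletion
#' @export
simulate_train_deterministic <- function(pool, protocol) {
  stopifnot(inherits(pool, "release_pool_params"),
            inherits(protocol, "stim_protocol"))
  refill_nA <- pool$r_pA_per_ms * protocol$ipi_ms / 1000
  p_k <- p_trajectory(pool, protocol)
  amps <- numeric(protocol$n_stim)
  N <- pool$N0_nA
  for (k in seq_len(protocol$n_stim)) {
    amps[k] <- p_k[k] * N
    N <- min(pool$N0_nA, N - amps[k] + refill_nA)
  }
  epsc_train(amps, protocol$ipi_ms)
}

#' Simulate a stochastic evoked EPSC train
#'
#' Quantal counterpart of [simulate_train_deterministic()]: the standing pool
#' is an integer vesicle count `M_k` (initially `round(1000 * N0 / q)`),
#' release at each stimulus is binomial with probability `p_k`, replenishment
#' between stimuli is Poisson with mean `1000 * r * ipi / q` vesicles (capped
#' at the initial count), and each released vesicle contributes an amplitude
#' drawn from Normal(q, q * q_cv) truncated at 0. Averaged over many trains
#' the result approaches the deterministic train.
#'
#' @inheritParams simulate_train_deterministic
#' @param seed Mandatory RNG seed; the same seed reproduces the same train.
#' @return An [epsc_train()].
#' @export
simulate_train_stochastic <- function(pool, protocol, seed) {
  stopifnot(inherits(pool, "release_pool_params"),
            inherits(protocol, "stim_protocol"))
  with_seed_required(seed, {
    M0 <- max(1L, as.integer(round(1000 * pool$N0_nA / pool$q_pA)))
    # r*ipi is already in pA of response-equivalent; one vesicle = q_pA
    refill_mean <- pool$r_pA_per_ms * protocol$ipi_ms / pool$q_pA
    p_k <- p_trajectory(pool, protocol)
    amps <- numeric(protocol$n_stim)
    M <- M0
    for (k in seq_len(protocol$n_stim)) {
      n_rel <- rbinom(1L, M, p_k[k])
      if (n_rel > 0L) {
        if (pool$q_cv > 0) {
          qs <- rnorm(n_rel, pool$q_pA, pool$q_pA * pool$q_cv)
          qs[qs < 0] <- 0
        } else {
          qs <- rep(pool$q_pA, n_rel)
        }
        amps[k] <- sum(qs) / 1000  # pA -> nA
      }
      M <- min(M0, M - n_rel + rpois(1L, refill_mean))
    }
    epsc_train(amps, protocol$ipi_ms)
  })
}
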