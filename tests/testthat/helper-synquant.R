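# shared fixtures built in code

# depletion-replenishment parameters at realistic calyx-scale values
pool_ctrl <- function() release_pool_params(N0_nA = 16.3, p = 0.44,
                                            r_pA_per_ms = 62.2,
                                            q_pA = 50, q_cv = 0.3)

proto_100hz <- function(n = 30) stim_protocol(n_stim = n, ipi_ms = 10)

# closed-form oracle for the deterministic depletion-replenishment recursion:
# E_k = r*ipi + (p*N0 - r*ipi) * (1-p)^(k-1)   (pool never re-capped at N0
# while depressing), giving cumulative intercept N0 - r*ipi/p and slope r*ipi
oracle_train_amplitudes <- function(N0, p, r_pA_per_ms, ipi_ms, n) {
  refill <- r_pA_per_ms * ipi_ms / 1000
  k <- seq_len(n)
  refill + (p * N0 - refill) * (1 - p)^(k - 1)
}

# brute-force two-sample KS distance over pooled observation points
ks_brute <- function(a, b) {
  pts <- sort(c(a, b))
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}
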