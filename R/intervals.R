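#' Empirical CDF of inter-event intervals
#'
#' Right-continuous step function `F(t) = #(intervals <= t) / n`, the
#' cumulative-probability representation used to compare spontaneous-release
#' interval distributions between conditions.
#'
#' @param intervals Positive intervals (ms), n >= 1.
#' @return An object of class `interval_ecdf`: list with sorted unique
#'   `support` and step `values`, plus `n`; also callable via [ecdf_eval()].
#' @export
interval_ecdf <- function(intervals) {
  if (length(intervals) == 0) stop("empty interval vector", call. = FALSE)
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("intervals must be positive and finite", call. = FALSE)
  }
  s <- sort(unique(intervals))
  v <- cumsum(tabulate(match(sort(intervals), s), length(s))) / length(intervals)
  structure(list(support = s, values = v, n = length(intervals)),
            class = "interval_ecdf")
}

#' Evaluate an empirical CDF
#'
#' @param e An [interval_ecdf()].
#' @param t Evaluation points.
#' @return `F(t)`, right-continuous.
#' @export
ecdf_eval <- function(e, t) {
  stopifnot(inherits(e, "interval_ecdf"))
  idx <- findInterval(t, e$support)
  ifelse(idx == 0, 0, e$values[pmax(idx, 1)])
}

#' Fit a hyperexponential mixture to interval data
#'
#' Least-squares fit of the two-component exponential mixture CDF
#' `F(t) = 1 - [w * exp(-t/tau_f) + (1 - w) * exp(-t/tau_s)]`
#' to the empirical CDF evaluated at the sorted observations — the same
#' procedure as fitting a double-exponential curve to a cumulative
#' probability plot. The optimiser is multi-start (log-spaced tau grids
#' crossed with w in {0.2, 0.5, 0.8}; >= 8 starts) over an unconstrained
#' parameterization (logit weight, log taus); identifiability is enforced by
#' ordering tau_fast < tau_slow in the result.
#'
#' @param intervals Positive intervals (ms), n >= 50.
#' @param n_starts Minimum number of starting points.
#' @return An object of class `hyperexp_fit`: `w_fast`, `tau_fast_ms`,
#'   `tau_slow_ms`, `rss`, `converged`, `percent_fast` (= 100 * w_fast).
#'   If no start converges the best attempt is returned with
#'   `converged = FALSE`.
#' @export
fit_hyperexponential <- function(intervals, n_starts = 9) {
  if (length(intervals) < 50) {
    stop("need at least 50 intervals for a stable mixture fit", call. = FALSE)
  }
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("intervals must be positive and finite", call. = FALSE)
  }
  t_sorted <- sort(intervals)
  n <- length(t_sorted)
  F_emp <- seq_len(n) / n

  obj <- function(par) {
    w <- stats::plogis(par[1])
    tf <- exp(par[2]); ts <- exp(par[3])
    resid <- F_emp - hyperexp_cdf(t_sorted, w, tf, ts)
    sum(resid^2)
  }

  m <- mean(t_sorted)
  tau_grid <- exp(seq(log(m / 8), log(m * 4), length.out = 3))
  starts <- list()
  for (w0 in c(0.2, 0.5, 0.8)) {
    for (tf0 in tau_grid) {
      starts[[length(starts) + 1L]] <- c(stats::qlogis(w0), log(tf0),
                                         log(tf0 * 4))
    }
  }
  if (length(starts) > n_starts && n_starts >= 9) {
    starts <- starts[seq_len(n_starts)]
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("hyperexponential fit failed from every start", call. = FALSE)
  }
  w <- stats::plogis(best$par[1])
  tf <- exp(best$par[2]); ts <- exp(best$par[3])
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; w <- 1 - w }
  structure(list(w_fast = w, tau_fast_ms = tf, tau_slow_ms = ts,
                 percent_fast = 100 * w, rss = best$value,
                 converged = best$convergence == 0, n = n),
            class = "hyperexp_fit")
}

#' @export
print.hyperexp_fit <- function(x, ...) {
  cat(sprintf(
    "hyperexponential fit (n = %d): tau_fast = %.3g ms (%.0f%%), tau_slow = %.3g ms, rss = %.3g\n",
    x$n, x$tau_fast_ms, x$percent_fast, x$tau_slow_ms, x$rss))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' Computes `D`, the maximum vertical difference between the two empirical
#' cumulative probability curves, exactly over the pooled observation points,
#' and an asymptotic p-value from the Kolmogorov distribution
#' `Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)` with
#' `lambda = (sqrt(n_e) + 0.12 + 0.11/sqrt(n_e)) * D` and effective size
#' `n_e = n1 * n2 / (n1 + n2)`.
#'
#' @param a,b Numeric samples (n >= 1 each).
#' @return List with `D`, `p_value`, `n1`, `n2`.
#' @examples
#' ks2(c(1, 2, 3, 4), c(2, 3, 4, 5))$D  # 0.25
#' @export
ks2 <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("samples must be finite", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  D <- max(abs(Fa - Fb))
  n_e <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(n_e) + 0.12 + 0.11 / sqrt(n_e)) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(D = D, p_value = min(1, max(0, p)), n1 = n1, n2 = n2)
}

#' Pointwise difference between two empirical CDFs
#'
#' Treatment-minus-control cumulative-probability difference curve evaluated
#' on a grid; values are bounded in `[-1, 1]` and its maximum absolute value
#' over the pooled support equals the two-sample KS statistic.
#'
#' @param ecdf_a,ecdf_b [interval_ecdf()] objects (A minus B).
#' @param grid Evaluation points (ms).
#' @return data.frame with `t_ms` and `difference`.
#' @export
cdf_difference <- function(ecdf_a, ecdf_b, grid) {
  stopifnot(inherits(ecdf_a, "interval_ecdf"),
            inherits(ecdf_b, "interval_ecdf"))
  data.frame(t_ms = grid,
             difference = ecdf_eval(ecdf_a, grid) - ecdf_eval(ecdf_b, grid))
}

#' Grubbs outlier screening
#'
#' Two-sided Grubbs test applied iteratively: at each pass the most extreme
#' point is tested with `G = max |x - mean| / sd` against the critical value
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` quantile of the t distribution with `n - 2` degrees of
#' freedom. If rejected, the point is removed and the test repeats (at most
#' `n - 3` passes, so at least three points always remain). A zero-variance
#' sample yields no outliers.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level (default 0.01).
#' @return List with `outlier_indices` (into the original vector), `G`
#'   (statistic per flagged point), `alpha`, `kept` (logical mask).
#' @export
grubbs <- function(values, alpha = 0.01) {
  if (length(values) < 3) stop("Grubbs test needs n >= 3", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  idx <- seq_along(values)
  flagged <- integer(0)
  G_flagged <- numeric(0)
  x <- values
  max_pass <- length(values) - 3L
  for (pass in seq_len(max(max_pass, 0L))) {
    n <- length(x)
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tq <- qt(1 - alpha / (2 * n), n - 2)
    G_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= G_crit) break
    worst <- which.max(dev)
    flagged <- c(flagged, idx[worst])
    G_flagged <- c(G_flagged, G)
    idx <- idx[-worst]
    x <- x[-worst]
  }
  kept <- !(seq_along(values) %in% flagged)
  list(outlier_indices = flagged, G = G_flagged, alpha = alpha, kept = kept)
}
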