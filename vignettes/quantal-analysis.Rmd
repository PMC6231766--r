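---
title: "Quantal analysis of presynaptic release: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of presynaptic release: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

## The problem

At a large glutamatergic terminal such as the calyx of Held, sustained
high-frequency firing depletes the readily releasable pool (RRP) of synaptic
vesicles, and transmission at steady state is carried by ongoing vesicle
replenishment. Three quantities summarize this machinery: the RRP size
(expressed here, as is conventional, in nA of summed postsynaptic current),
the release probability `Pr` (fraction of the standing pool released per
stimulus), and the replenishment rate (pA/ms of response-equivalent).
None is directly observable; all are inferred from the shape of evoked EPSC
trains. Alongside evoked release, the timing of spontaneous miniature EPSCs
(mEPSCs) carries independent information about the release machinery, and
two-channel fluorescence colocalization localizes molecular components to
the presynaptic compartment. `synquant` implements these estimators together
with generative simulators so each one can be validated against known ground
truth.

## The release model

The simulators use a depletion–replenishment model. The standing pool `N_k`
(nA) starts at `N0`; stimulus `k` releases

    E_k = p_k * N_k,      N_{k+1} = min(N0, N_k - E_k + r * ipi)

with `r` the replenishment rate and `ipi` the inter-pulse interval. The cap
at `N0` encodes a finite standing pool — replenishment refills but never
overfills, which is the assumption that licenses back-extrapolating the
cumulative EPSC to a fixed intercept. With facilitation off (`p_k = p`), the
recursion solves in closed form:

    E_k = r*ipi + (p*N0 - r*ipi) * (1-p)^(k-1)

so amplitudes decay geometrically to the fixed point `E* = r*ipi`, and the
cumulative response approaches the line

    C_k ≈ (N0 - r*ipi/p) + (r*ipi) * k .

These two expressions are the package's internal oracle: the cumulative-EPSC
estimator must return intercept `N0 - r*ipi/p` and slope `r` on noise-free
trains, and the exponential-decay estimator must recover `p` exactly, because
`e^(-1/tau) = 1 - p`.

The stochastic mode replaces the mean-field pool with an integer vesicle
count `M_k` (initially `round(1000*N0/q)` for quantal size `q` in pA),
binomial release, Poisson replenishment with mean `r*ipi/q` vesicles per
interval, and per-vesicle amplitudes `Normal(q, q*cv)` truncated at zero.
Averaged over trains it converges to the deterministic model, which is what
the stochastic-recovery tests assert. Every stochastic function takes an
explicit seed and touches no global RNG state.

Optional facilitation adds a decaying increment to `p` per stimulus
(`facilitation_df`, decay `tau_f_ms`). It is off by default and exists to
exercise the facilitation-correction branch of the exponential estimator;
no claim is made that it models the biophysics of residual calcium.

## The two RRP estimators

**Cumulative-EPSC back-extrapolation** (`estimate_quantal_train`). A
least-squares line through `(k, C_k)` over a steady-state window gives the
replenishment rate (slope per stimulus, divided by `ipi` to yield pA/ms) and
the RRP (intercept at `k = 0`). `Pr1 = P1/RRP`. Two conventions were open:

* *Fit window.* The default is stimuli 20–30; 15–30 is an equally defensible
  choice and is supported via the `window` argument. At steady state the two
  agree to within the residual depletion transient.
* *Abscissa.* Regression is on stimulus number with the intercept evaluated
  at `k = 0`. This convention makes the depletion-only oracle exact; using
  time as abscissa only rescales the slope.

The window semantics matter for exactness claims: the fitted line ignores
the depletion transient `(1-p)^k`, so "exact" recovery holds only when the
window lies deep enough that the transient is negligible — at `p = 0.44`
the stimulus-20 transient is ~1e-5 of `N0`, and the grid tests that assert
1e-9-level agreement push the window to stimuli 150–200 where the transient
is below machine noise for every `p ≥ 0.2`.

**Exponential decay** (`estimate_pr_exponential`). `P_k` against stimulus
number is fit by `P_ss + A*e^(-(k-1)/tau)`; `Pr = 1 - e^(-1/tau)`. The fit
is profiled: for fixed `tau` the linear coefficients have a closed-form
solution, leaving a one-dimensional optimization in `tau` — more robust than
a three-parameter nonlinear search and exact to optimizer tolerance on clean
trains. The fit uses stimuli 2 onward and is extrapolated back to stimulus 1
to obtain `RP0`. This choice makes the facilitation correction
self-consistent: when the observed first response `R0` sits below the curve
(paired-pulse facilitation), `Fc = RP0/R0` is computed from a curve that the
anomalous first point has not itself dragged down, and `Pr` is divided by
`Fc`. On non-facilitating trains the exclusion of the first point changes
nothing, because that point lies on the same exponential. The implied pool
is `RRP = RP0/Pr`, the pure-depletion relation `E1 = Pr*N0` applied to the
fitted initial value; the formula is one consistent choice among several the
literature leaves unstated.

Group statistics are computed per cell first and then averaged
(`group_mean_sem`); the group mean of per-cell `Pr` estimates is not the
ratio of group-mean `P1` to group-mean RRP.

## Spontaneous release

Inter-event intervals are modelled as a hyperexponential: with probability
`w_fast` an interval is exponential with mean `tau_fast_ms`, otherwise
`tau_slow_ms`. The generator's default condition (`w = 0.64`,
`tau_fast = 170` ms, `tau_slow = 740` ms) corresponds to a spontaneous rate
of about 2.7 Hz with a dominant fast component, a regime typical of a
protein-synthesis-inhibited terminal; the slow mean sits somewhat above four
times the fast mean, matching the qualitative ">4-fold slower" separation of
the two populations.

`fit_hyperexponential` fits the mixture CDF to the empirical CDF at the
sorted observations by least squares — the same operation as fitting a
double-exponential to a cumulative probability plot — rather than by
interval MLE, so that the fitted object is exactly what the cumulative plot
shows. The optimizer runs from nine starting points (three log-spaced `tau`
grids crossed with `w` in {0.2, 0.5, 0.8}) on an unconstrained scale (logit
`w`, log `tau`s), and identifiability is enforced by ordering
`tau_fast < tau_slow` afterwards. At `n = 5000` the estimator's sampling
error is comparable to the ±0.05 / ±10% recovery tolerances, so recovery is
asserted on means over seeded replicates (and the median |w error|), not on
a single draw. Percent contributions are reported as `100*w_fast`.

Two caveats the synthetic data does not cover: real mEPSC trains are not a
renewal process after tetanic stimulation (rates relax over seconds), and
per-group fits here are unconstrained — no time constant is shared across
experimental groups.

## Mini detection

`detect_minis` re-implements classical threshold-based mini detection with
deterministic rules (no interactive inspection step): a trailing 50 ms
running-median baseline (computed as a centered running median shifted by
half a window, which is equivalent and fast), threshold crossings of the
baseline-relative signal in the stated polarity, extremum search within
20 ms, local baseline over 2 ms ending 5 ms before the peak, 3-point peak
averaging, 10–90% rise by linear interpolation, half-decay within 5 ms, and
an event-window area with a 10 pA·ms floor. Candidate peaks closer than one
search window keep only the larger extremum — the parameter set assumes
isolated events. Because the half-decay definition and a 10–90% decay time
are both in circulation, both are emitted per event (`decay_half_ms`,
`decay_10_90_ms`).

On noise-free rendered traces with events ≥ 20 pA separated by ≥ 50 ms the
detector is exact (recall and precision 1.0); with realistic noise (2 pA SD)
it misses the events that fall below the 10 pA threshold, which is the
detector working as specified, not failing.

## Colocalization

Background subtraction (`max(I - 16, 0)`, 8-bit clamping semantics) precedes
correlation, matching the conventional ordering; `pearson_coloc` exposes
both raw and background-subtracted modes because published r-values do not
always state which was used. Pearson r is computed over ROI pixels only,
with no Costes-style thresholding. Line profiles use bilinear interpolation
with 1-pixel sampling width. The image synthesizer constructs channel B as
`r*A_std + sqrt(1-r^2)*eps` with `eps` orthogonalized against A, so the
sample correlation equals the target exactly before clipping to [0, 255];
with the default intensity statistics (mean 100 + background 16, SD 30)
clipping is rare and the realized r stays within 0.02 of target. Gaussian
fields have no spatial structure — they validate the correlation estimator,
not segmentation or ROI drawing.

## Numerical choices and problem sizes

* KS2 p-values use the asymptotic Kolmogorov series with
  `lambda = (sqrt(n_e) + 0.12 + 0.11/sqrt(n_e)) * D`,
  `n_e = n1*n2/(n1+n2)`; `D` itself is exact over the pooled support. No
  exact small-sample p-value is attempted.
* Grubbs screening iterates at most `n - 3` times (one removal per pass), so
  at least three points always remain; α defaults to 0.01.
* Zero-variance inputs (flat ROI, constant interval vector) raise explicit
  errors or return "no outliers" rather than propagating NaN.
* Test-suite problem sizes — 500 Monte-Carlo trains for the steady-state
  check, 200 stochastic trains for recovery, 20 seeds × 5000 intervals for
  the mixture fits, 100-event detector suites, 256×256 images — were chosen
  so that sampling error sits well inside each asserted tolerance while the
  full suite stays fast enough to run routinely.

## Limitations

The simulators deliberately omit calcium dynamics, action-potential
waveforms, series-resistance and filtering artifacts, receptor
desensitization/saturation, and any mechanism for post-tetanic modulation of
spontaneous release; time-varying interval parameters can be emulated by
concatenating segments, but no mechanistic model is provided. Passing the
recovery tests therefore shows the estimators are correct for the stated
generative model, not that the model captures every property of recorded
data.
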