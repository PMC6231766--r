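Package: synquant
Title: Quantal Analysis of Presynaptic Release at High-Fidelity Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of presynaptic vesicle release from
    voltage-clamp recordings. Provides a depletion-replenishment simulator of
    evoked EPSC trains, a hyperexponential renewal-process generator of
    spontaneous (miniature EPSC) events with trace rendering, threshold-based
    mini detection with per-event shape statistics, inter-event-interval
    statistics (empirical CDFs, double-exponential mixture fits, a two-sample
    Kolmogorov-Smirnov statistic computed over the pooled support, Grubbs
    outlier screening), train quantal analysis (paired-pulse ratio,
    cumulative-EPSC back-extrapolation of the readily releasable pool, release
    probability and replenishment rate, exponential-decay release-probability
    estimation with facilitation correction), and ROI-based two-channel
    colocalization (background subtraction, Pearson correlation, line-scan
    profiles). A configuration-driven pipeline ties the stages together so
    every analysis is testable end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    tiff,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
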