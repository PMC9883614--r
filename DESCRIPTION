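Package: pathwaydyn
Title: Temporal Dynamics and Directed Interactions of EEG Channel Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising when and in what direction category
    information flows between groups of EEG channels, built around the
    dorsal/ventral visual-pathway question. Provides a synthetic generator of
    epoched multichannel EEG-like data with known embedded onset latencies and
    directed inter-region coupling, a preprocessing chain (zero-phase
    filtering, decimation, average re-referencing, bad-channel and artifact
    rejection, epoching), validation of region channel groups (PCA loading
    distances, hierarchical clustering, signal-to-noise ratios), time-resolved
    support-vector-machine category decoding with exemplar-level
    cross-validation and bootstrap onset-latency statistics, multivariate
    Granger causality between channel groups over concatenated per-object
    timeseries, and time-generalized representational similarity analysis with
    a mirrored-subtraction directionality statistic and partial-correlation
    controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
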