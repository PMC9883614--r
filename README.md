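# pathwaydyn

Tools for asking *when* category information appears in different groups of
EEG channels and *which group drives which*, built around the question of
whether the dorsal (parietal) visual pathway precedes and predicts the
ventral (occipitotemporal) pathway during object recognition.

The package bundles three complementary analyses of epoched, multichannel
EEG data with per-trial category and exemplar labels:

1. **Time-resolved category decoding with exemplar-level cross-validation.**
   At every timepoint *t* a linear support-vector machine is trained on the
   channel pattern of 3 of each category's 5 exemplars and tested on trials
   of the 2 held-out exemplars, so above-chance accuracy requires
   generalization across exemplars. The **decoding onset** of a region is
   the earliest post-stimulus time at which a one-sided t-test against
   chance is significant for at least two consecutive timepoints; its
   uncertainty is measured by resampling participants with replacement
   (bootstrap onset distributions), and region ordering is tested with an
   exact binomial test on the proportion of paired resamples in which one
   region's onset precedes the other's. Control analyses (leave-one-
   category-out, channel resampling, residualization against the rest of
   the montage's principal components) probe the robustness of the
   ordering.

2. **Multivariate Granger causality between channel groups.** Each object's
   trial-averaged channel-by-time response over the stimulus period is
   concatenated (with separators that no regression window may cross) into
   one series per region; nested vector autoregressions on the leading
   principal components give, per direction, an F statistic from the
   generalized-variance ratio of restricted vs. full residual covariances,
   with each direction's best-fitting lag (max lag 50 ms). The directional
   **F-difference** `F(A→B) − F(B→A)` is compared to zero across
   participants with a Wilcoxon signed-rank test.

3. **Time-generalized representational similarity.** Per timepoint, a
   20 × 20 cosine-similarity matrix between object responses (RDM); the
   time-generalization matrix correlates region A's RDM at *t₁* with region
   B's at *t₂* for all pairs. The **mirrored-subtraction statistic**
   (each above-diagonal cell minus its mirror) is positive when A's
   geometry predicts B's *future* geometry; rank-ordering of correlations,
   a rolling binomial test against the analytic chance proportion
   `(T−1)/2T`, and partial correlations controlling a third region's RDM
   complete the analysis.

Because the motivating dataset is available only from its original
investigators, the package ships a **synthetic EEG generator**
(`generator_config()`, `simulate_cohort()`) that emulates the study's
structure — 4 categories × 5 exemplars × 84 repetitions, 250 Hz, −48…500 ms
epochs, region channel groups — with known embedded ground truth:
region-specific onset latencies, stimulus-locked representational dynamics,
and lagged dorsal→ventral coupling. Every statistic above can therefore be
validated against parameters that are known exactly. A preprocessing chain
(`bandpass()`, `downsample()`, `rereference_average()`,
`detect_bad_channels()`, `epoch()`, `reject_epochs_threshold()`) and region
validation tools (`functional_distinctness()`, `snr_timecourse()`,
`snr_baseline()`) cover the path from continuous recordings to epochs.

## Worked example

Simulate a small cohort with a dorsal onset of 60 ms, a ventral onset of
88 ms and dorsal→ventral coupling at a 20 ms lag, then recover the onset
ordering and the coupling direction:

```r
library(pathwaydyn)

cfg <- generator_config(
  n_participants = 8, n_reps = 84,
  montage = make_montage(c(dorsal = 10, ventral = 10)),
  signals = list(dorsal  = list(onset_ms = 60, amplitude = 0.3),
                 ventral = list(onset_ms = 88, amplitude = 0.3)),
  coupling = list(source = "dorsal", target = "ventral",
                  lag_ms = 20, gain = 0.7),
  seed = 3)
cohort <- simulate_cohort(cfg)

res_d <- decode_cohort(cohort, "dorsal",  n_folds = 50, fold_seed = 1)
res_v <- decode_cohort(cohort, "ventral", n_folds = 50, fold_seed = 2)
on_d <- bootstrap_onsets(res_d, n_boot = 500, seed = 9)
on_v <- bootstrap_onsets(res_v, n_boot = 500, seed = 9)
on_d$median_onset_ms
#> [1] 68
on_v$median_onset_ms
#> [1] 88
pr <- precedence_binomial(on_d, on_v)
c(pr$proportion_a_first, pr$p_value)
#> [1] 9.111111e-01 4.149753e-86

gg <- group_granger(cohort, c("dorsal", "ventral"), n_components = 5)
gg$group
#> $W
#> [1] 36
#> $p
#> [1] 0.0078125
#> $d
#> [1] 1.985855

mats <- lapply(cohort, function(ep) {
  timegen_matrix(compute_rdm_series(ep, "dorsal"),
                 compute_rdm_series(ep, "ventral"))
})
ms <- mirror_statistic(mats)
round(c(mean = ms$mean, t = ms$t, p = ms$p, d = ms$d), 4)
#>   mean      t      p      d
#> 0.0095 6.0180 0.0005 2.1277
```

The recovered onset medians sit at or one to two samples after the embedded
60/88 ms latencies (the response ramps up over ~20 ms, so the first
*detectable* sample can trail the true onset), the dorsal region precedes
the ventral region in 91% of paired bootstrap resamples, the Granger
F-difference is positive for all 8 participants (W = 36 is the maximal
signed-rank statistic for n = 8), and the mirrored time-generalization
statistic is significantly positive — all three analyses recover the
embedded dorsal→ventral direction. The run takes a few minutes on one CPU.

The full pipeline (simulate → regions → decode → granger → timegen) with
machine-readable outputs:

```r
cfg <- pipeline_config(generator = generator_config(n_participants = 6,
                                                    n_reps = 4, seed = 1),
                       decode = list(n_folds = 10, n_boot = 200),
                       output_dir = "run1", master_seed = 7)
run_pipeline(cfg)
summarize_pipeline("run1")
```

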