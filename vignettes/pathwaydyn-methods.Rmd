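---
title: "Methods: temporal dynamics and directed interactions of EEG channel groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal dynamics and directed interactions of EEG channel groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the synthetic-data generator, the
numerical choices and the known limitations of `pathwaydyn`. It is the
package's reference for *why* each analysis is built the way it is; the
README shows how to run them.

## The scientific question

Object category information can be decoded from both the dorsal (parietal)
and the ventral (occipitotemporal) visual pathway. The package implements
three analyses that together ask whether one pathway *leads*: onset-latency
comparison of time-resolved decoding, directed (Granger) prediction between
the pathways' multichannel timeseries, and time-generalized
representational similarity, which asks whether one region's
representational geometry predicts the other's *future* geometry.

## The synthetic generator

Real data of this kind are rarely redistributable, so every analysis here
is validated against a generator whose ground truth is known exactly.
`generator_config()` encodes the study design the package emulates: 4
categories × 5 exemplars × 84 repetitions per exemplar (420 trials per
category), 250 Hz sampling, epochs spanning −48…500 ms with stimulus onset
at 0 ms and offset at 300 ms. The time grid is anchored at 0 ms (samples at
−48 + 4k ms), so a 250 Hz grid cannot also contain −50 ms; the nominal
50 ms pre-stimulus baseline is represented by 12 pre-stimulus samples.

**Signal model.** Each region with a signal specification carries, from its
onset latency to the stimulus offset, a category- and exemplar-specific
channel pattern scaled by `amplitude` and by a response envelope that ramps
up over ~20 ms (the envelope is already non-zero at the onset sample, so
the embedded onset is exactly the first sample with non-zero
between-category variance — verifiable by a direct scan, independent of any
analysis). The pattern has a hierarchical structure:

* a static unit-norm category pattern shared by the category's exemplars,
  plus a static exemplar perturbation of relative magnitude `exemplar_sd`
  (default 0.3) — this is what exemplar-split decoding generalizes over;
* a stimulus-locked *drift*: a smooth random process (boxcar-smoothed white
  noise, width `drift_smooth_ms`, default 8 ms) added to the pattern with
  relative magnitude `drift_scale` (default 2.5) at the category level plus
  `drift_scale * exemplar_sd` at the exemplar level, then renormalized.

The drift makes the representational geometry evolve over the response
window, as empirical temporal-generalization matrices show real geometry
does (decoding generalizes poorly across distant timepoints). It is drawn
per participant (stimulus-locked: shared across that participant's trials).
Without it, a static geometry makes the time-generalization matrix
symmetric up to noise and leaves a vector autoregression nothing to
predict, so neither directed analysis could recover an embedded lag; with
it, both can, and the embedded lag is identifiable to one sample at high
SNR.

**Coupling.** A directed interaction is injected by mixing the source
region's noiseless template, shifted by `lag_ms`, into the target's
channels. The mixture is energy-preserving — the target's own template is
scaled by `sqrt(1 − gain²)` and the lagged source enters with weight
`gain` — so coupled and uncoupled regions have identical signal energy and
hence matched SNR. This matters because the correlated vectors in the
time-generalization analysis literally include the RDM diagonal (see
below): a region with excess signal energy would bias the mirrored
statistic through that shared-diagonal component alone. `gain` defaults to
0.7 (≈ half the target's signal variance is inherited from the source).

**Noise** is per-channel, per-trial Gaussian with standard deviation
`white_sd` (default 1) of which a fraction `pink_fraction` (default 0.5)
has a 1/f spectrum (FFT-shaped, analytically normalized to unit variance).
The default amplitude 0.3 was chosen so that single-trial 4-category
decoding peaks in the low-0.30s against a 0.25 chance level — the regime
the motivating literature reports — rather than saturating.

The generator produces no category-*common* evoked deflection, so
trial-averaged signal-to-noise ratios are near zero in magnitude; the
property the region-validation analysis relies on — that regions do *not
differ* in SNR — holds by construction and is what the tests assert.

**Determinism.** Every dataset is a pure function of `(config$seed,
participant_seed)`; static patterns derive from the config seed (shared
across the cohort), drift and noise from participant-derived seeds. Derived
seeds are produced by a Lehmer-style mixer kept below 2³¹.

## Preprocessing

Filtering is zero-phase (forward–backward) with 4th-order Butterworth
designs; zero-phase matters because any group delay would bias onset
estimates. The 0.1 Hz high-pass sits four decades below a 1000 Hz Nyquist,
where the polynomial transfer function's DC zero is destroyed by
coefficient rounding (≈0.3% DC leakage per pass); the numerator is
therefore snapped to its exact binomial form, and channels are demeaned
before filtering, making the DC response exactly zero. Decimation low-pass
filters at 80% of the target Nyquist and keeps every k-th sample; event
indices are rescaled to the new grid. Bad channels are *dropped*, not
interpolated (flatline ≥ 5 s, or best absolute correlation with any other
channel below 0.8). Epoching anchors the window's grid at each event
sample; baseline correction (on by default) subtracts each trial/channel's
pre-stimulus mean — the motivating methods describe a baseline period
without stating a subtraction, and the default is the field's convention.
Artifact rejection removes whole trials whose absolute amplitude exceeds a
threshold (default ±100 µV-like units, a conventional value).

## Region validation

`functional_distinctness()` runs PCA per participant with timepoints of the
trial-averaged response as observations and channels as variables, so
loadings live in channel space. Loadings are scaled by component standard
deviation times `sqrt(n − 1)`; with all components retained, Euclidean
distances between channels' loading vectors then equal full-space distances
between centered channel timecourses exactly. Distances are averaged over
participants, clustered with average linkage, and the tree is cut at the
number of regions. Purity is the fraction of channels whose cluster maps —
by nearest region centroid in the classical-MDS embedding of the averaged
distances — to their own region. Because that mapping is data-adaptive,
its chance level is *above* the naive 1/region count (a cluster's own
members pull their region's centroid toward it); the tests therefore
compare null-data purity against a permutation-derived Monte-Carlo chance
level rather than a hard-coded constant.

Both SNR definitions are implemented: mean/sd of the trial-averaged
timecourse, and stimulus-period mean over pre-stimulus baseline sd, each
averaged over a region's channels (arithmetic mean; the aggregation is a
package choice).

## Decoding and onset statistics

The classifier is a linear SVM (one-vs-rest, hinge loss, C = 1) trained by
dual coordinate descent, with features standardized per fold and timepoint
using training-set statistics and the bias handled as an augmented
constant feature. The optimizer runs at most 15 passes with the projected-
gradient stopping tolerance 0.1 (the LIBLINEAR default for dual solvers);
fold-averaged accuracy curves at 15 vs. 50 passes agree to < 0.005 in the
stimulus window and the label-shuffled null stays at chance, while the
runtime halves. Training and testing use single-trial patterns; "100-fold
cross-validation" is implemented as 100 seeded draws without replacement
from the 10⁴ possible joint exemplar splits (C(5,3) = 10 per category).

`bootstrap_onsets()` resamples participants with replacement; on each
resample a one-sided one-sample t-test against chance is computed per
timepoint (per-resample variance), and the onset is the earliest
post-stimulus timepoint opening a run of ≥ 2 consecutive significant
timepoints. The onset search starts at 0 ms because pre-stimulus decoding
is definitionally spurious. Timepoints with zero between-participant
variance are treated as significant iff the mean exceeds chance.
Precedence between two regions uses one shared resampling of participants
for both regions (paired draws), excludes ties and double-"none" resamples,
counts single-"none" resamples for the region with an onset, and tests the
a-first count with an exact two-sided binomial against 0.5.

One calibration subtlety the tests make explicit: the bootstrap conditions
on the cohort, so a *single* cohort's precedence proportion under an
exchangeable null is not a ~0.5 ± binomial-error quantity — its
cohort-to-cohort spread is large (sd ≈ 0.2) because each finite cohort has
an idiosyncratic region asymmetry. The acceptance machinery therefore pools
paired resamples over many independent small cohorts, which is calibrated.
Similarly, the percentile bootstrap CI is slightly anti-conservative at
n ≈ 10–20 participants (one-sided miscoverage ≈ 5% rather than 2.5%), a
known small-sample property the tests assert at its empirical level.

## Granger causality

`concat_object_series()` builds, per region, the trial-averaged
channel × time response of each of the 20 objects over 0–300 ms (76
samples), concatenated in fixed object order with a single separator
between objects. Separators implement exclusion semantics: any regression
row whose lag window covers a separator is dropped, so no model ever
predicts across an object boundary; at order p this leaves exactly
`n_objects × (76 − p)` rows.

Each region is reduced to its top k principal components (default 10,
capped at the channel count) before fitting. For each direction and every
order p up to 50 ms, a restricted model (intercept + target's own p lags)
is compared with a full model (+ predictor's p lags) by least squares; the
F statistic is `((|Σr|/|Σf|)^(1/m) − 1) · df2/df1` with m target
components, df1 the added coefficients per equation and df2 the residual
degrees of freedom — which reduces exactly to the classical nested-
regression F for a univariate target (the test suite checks this against a
brute-force oracle at 10⁻⁸). Each direction uses its *best-fitting lag*,
the order maximizing that direction's F. An information-criterion rule was
evaluated first and rejected: at this problem's scale the BIC penalty
dominates and always selects order 1, which is blind to any embedded lag
beyond one sample. Maximizing F is applied identically to both directions,
so the F-difference remains exactly antisymmetric under region swap and its
null distribution stays centered (verified by a uniformity test on group
p-values over null cohorts). The estimability floor requires more valid
rows than full-model coefficients per equation; at the defaults the
rows-per-coefficient ratio is ≈ 5, which is accepted (a 10× ratio is
unattainable with 20 objects and k = 10).

The group test is a Wilcoxon signed-rank of per-participant F-differences
against zero (zero differences dropped, with a message), with effect size
d = mean/sd. The sign convention is `f_difference = F(predictor→target) −
F(target→predictor)`, positive meaning the predictor region dominates.

## Time-generalized representational similarity

RDMs store cosine similarities (what the underlying methods compute; the
"dissimilarity" name is conventional — correlations are invariant to the
affine flip, which a test asserts). The correlated vectors are the upper
triangle *including the diagonal*, implemented literally as described in
the motivating methods. The constant diagonal is not harmless: both
vectors contain 1s at the same 20 coordinates, which inflates every
correlation (independent noise-RDMs correlate ≈ 0.5 through that shared
pattern alone) and is symmetric between regions only when region signal
energies match — one reason the generator's coupling is energy-preserving.

The mirror statistic averages, over all above-diagonal cells (region A's
time on rows), the cell minus its mirror across the diagonal; per-
participant means are tested against zero with a one-sample t-test
(degenerate zero-spread inputs return the statistic with an undefined t
rather than an error). Ranking sorts all cells by correlation (ties broken
by earlier A-time, then earlier B-time — ties are not otherwise specified
anywhere); the rolling binomial compares the a-leads share of the top w
cells against the analytic null `(T − 1)/2T` — computed from the matrix
geometry, so non-default windows stay correct; for T = 88 it is 87/176 ≈
0.494, printed as 0.49. Partial correlations control the covariate
region's RDM at the *A-axis* timepoint; a residual-regression oracle pins
the formula in the tests. Group-level ranking uses the participant-
averaged matrix while the t-test uses per-participant matrices, matching
how such analyses are conventionally split between visualization and
inference.

## Problem sizes used by the tests and the acceptance script

The packaged checks run on one CPU and scale the cohorts accordingly: null
decoding calibration uses 12 participants × 20 trials/exemplar with the
28-channel region pair; onset recovery uses 20 participants (medians
recovered within ±8 ms of the embedded 60/88 ms; the ~20 ms ramp places
first detectability one to two samples after the true onset); the
exchangeable-onset null pools 24 cohorts of 8 participants; Granger null
calibration uses 50 cohorts of 6 participants at reduced channel counts;
time-generalization direction recovery uses cohorts at the full 84
repetitions (trial-averaged RDMs are cheap even when decoding is not), and
lag recovery to ±1 sample is asserted at high SNR (amplitude 1.5), where
the generator's ground truth is cleanly identifiable.

## Limitations

* The generator is a statistical emulation — random channel patterns,
  stationary pink-plus-white noise, no biophysical forward model, no eye
  blinks, no evoked (category-common) deflection — so passing tests
  demonstrate the *statistical machinery* recovers embedded structure, not
  that real cortical dynamics satisfy the model.
* ICA-based artifact removal and electrode-atlas localization are out of
  scope; region membership is whatever the montage says.
* Granger causality is pairwise (two regions at a time), time-domain only,
  and runs on PCA-reduced series; conditional multi-region models and
  spectral variants are not provided.
* The literal inclusion of the RDM diagonal inflates time-generalization
  correlations toward a common baseline; the mirrored statistic subtracts
  it out in expectation, but single-cell rankings carry that shared
  variance.
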