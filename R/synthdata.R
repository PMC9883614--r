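#' Configuration for the synthetic EEG generator
#'
#' Assembles and validates the full parameter set for simulating a cohort of
#' epoched, multichannel EEG-like datasets with known category structure,
#' region-specific onset latencies and directed inter-region coupling.
#'
#' The default design mirrors the object-viewing study the package is built
#' around: 4 categories x 5 exemplars x 84 repetitions per exemplar, 250 Hz
#' sampling, epochs from -48 to 500 ms (stimulus onset at 0 ms, offset at
#' 300 ms). Category-discriminative signals switch on at region-specific
#' latencies (dorsal before ventral), and the dorsal response is propagated
#' into the ventral channels at a fixed lag, giving every downstream analysis
#' a known ground truth.
#'
#' @param n_participants Number of simulated participants.
#' @param n_categories Number of stimulus categories.
#' @param n_exemplars Exemplars per category.
#' @param n_reps Repetitions per exemplar (trials per exemplar).
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_window Length-2 ms window; the time grid is anchored at 0 so
#'   both stimulus onset (0 ms) and offset (300 ms) fall on samples.
#' @param signals Named list mapping region name to
#'   `list(onset_ms =, amplitude =)`. Regions without an entry carry noise
#'   only. `onset_ms` must lie inside the epoch window; `amplitude >= 0`
#'   scales the unit-norm category pattern.
#' @param coupling `NULL`, or a list `list(source =, target =, lag_ms =,
#'   gain =)` describing lagged linear propagation of the source region's
#'   noiseless signal into the target region's channels. The coupled signal
#'   is mixed in energy-preservingly — the target's own template is scaled
#'   by `sqrt(1 - gain^2)` and the lagged source template enters with weight
#'   `gain` — so the target region keeps the same signal energy (and hence
#'   SNR) as an uncoupled region, matching the SNR equivalence across
#'   regions that the analyses assume. `gain` in `[0, 1]` is the coupled
#'   amplitude share; `lag_ms` must be in `[0, 50]`.
#' @param noise `list(white_sd =, pink_fraction =)`: per-channel noise
#'   standard deviation and the fraction of noise variance given a 1/f
#'   (pink) spectrum.
#' @param exemplar_sd Relative magnitude of the exemplar-specific pattern
#'   perturbation added to the shared category pattern.
#' @param drift_scale Relative magnitude of the smooth, stimulus-locked
#'   category-pattern drift that makes the representational geometry evolve
#'   over the response window (0 = static patterns). The drift is shared
#'   across trials and participants, emulating stimulus-driven dynamics, and
#'   is what makes an embedded coupling lag recoverable by time-generalized
#'   analyses.
#' @param drift_smooth_ms Boxcar smoothing width of the drift process.
#' @param stimulus_offset_ms Time at which the evoked response ends.
#' @param montage An `eeg_montage`; defaults to [make_montage()].
#' @param seed Master integer seed; all randomness derives from it.
#' @return A validated list of class `generator_config`.
#' @seealso [simulate_participant()], [simulate_cohort()]
#' @export
generator_config <- function(n_participants = 20,
                             n_categories = 4,
                             n_exemplars = 5,
                             n_reps = 84,
                             sampling_rate = 250,
                             epoch_window = c(-48, 500),
                             signals = list(
                               occipital = list(onset_ms = 60, amplitude = 0.3),
                               dorsal    = list(onset_ms = 60, amplitude = 0.3),
                               ventral   = list(onset_ms = 88, amplitude = 0.3),
                               frontal   = list(onset_ms = 108, amplitude = 0.3)
                             ),
                             coupling = list(source = "dorsal",
                                             target = "ventral",
                                             lag_ms = 20, gain = 0.7),
                             noise = list(white_sd = 1, pink_fraction = 0.5),
                             exemplar_sd = 0.3,
                             drift_scale = 2.5,
                             drift_smooth_ms = 8,
                             stimulus_offset_ms = 300,
                             montage = make_montage(),
                             seed = 1L) {
  counts <- c(n_participants = n_participants, n_categories = n_categories,
              n_exemplars = n_exemplars, n_reps = n_reps)
  if (any(counts < 1)) stop("all counts must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(epoch_window) != 2 || epoch_window[1] >= epoch_window[2]) {
    stop("epoch_window must be an increasing ms pair")
  }
  step <- 1000 / sampling_rate
  times <- time_grid(epoch_window, sampling_rate)
  for (rg in names(signals)) {
    sp <- signals[[rg]]
    if (is.null(sp$onset_ms) || is.null(sp$amplitude)) {
      stop(sprintf("signal spec for region '%s' needs onset_ms and amplitude", rg))
    }
    if (sp$amplitude < 0) stop("signal amplitude must be >= 0")
    if (sp$onset_ms < epoch_window[1] || sp$onset_ms > epoch_window[2]) {
      stop(sprintf("onset_ms for region '%s' outside the epoch window", rg))
    }
    if (sp$amplitude > 0) region_channels(montage, rg, min_channels = 1L)
  }
  if (!is.null(coupling)) {
    if (coupling$gain < 0 || coupling$gain > 1) {
      stop("coupling gain must be in [0, 1] (coupled amplitude share)")
    }
    if (coupling$lag_ms < 0 || coupling$lag_ms > 50) {
      stop("coupling lag_ms must be in [0, 50]")
    }
    if (coupling$lag_ms > diff(epoch_window)) {
      stop("coupling lag exceeds the epoch length")
    }
    region_channels(montage, coupling$source)
    region_channels(montage, coupling$target)
  }
  if (noise$pink_fraction < 0 || noise$pink_fraction > 1) {
    stop("pink_fraction must be in [0, 1]")
  }
  if (drift_scale < 0) stop("drift_scale must be >= 0")
  cfg <- list(n_participants = as.integer(n_participants),
              n_categories = as.integer(n_categories),
              n_exemplars = as.integer(n_exemplars),
              n_reps = as.integer(n_reps),
              sampling_rate = sampling_rate,
              epoch_window = epoch_window,
              times = times,
              signals = signals,
              coupling = coupling,
              noise = noise,
              exemplar_sd = exemplar_sd,
              drift_scale = drift_scale,
              drift_smooth_ms = drift_smooth_ms,
              stimulus_offset_ms = stimulus_offset_ms,
              montage = montage,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# sample grid anchored at 0 ms so onset/offset land on samples
time_grid <- function(window, sampling_rate) {
  step <- 1000 / sampling_rate
  k_lo <- ceiling(window[1] / step)
  k_hi <- floor(window[2] / step)
  seq(k_lo, k_hi) * step
}

# deterministic 31-bit seed stream derived from (master, k); Lehmer-style,
# kept < 2^31 so it is always a valid set.seed() argument
derive_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.double(master) %% m) + 1
  s <- (s * 16807) %% m
  s <- (s + as.double(k) * 69621) %% m
  as.integer((s * 16807) %% m)
}

# static category/exemplar channel patterns for one region: shared unit-norm
# category pattern plus a smaller exemplar-specific perturbation
make_patterns <- function(n_ch, n_categories, n_exemplars, exemplar_sd) {
  pats <- array(0, dim = c(n_ch, n_categories, n_exemplars))
  for (cc in seq_len(n_categories)) {
    p <- stats::rnorm(n_ch)
    p <- p / sqrt(sum(p^2))
    for (ee in seq_len(n_exemplars)) {
      q <- stats::rnorm(n_ch)
      q <- q / sqrt(sum(q^2))
      pats[, cc, ee] <- p + exemplar_sd * q
    }
  }
  pats
}

# smooth stimulus-locked drift sheet [channel x time]: boxcar-smoothed white
# noise rescaled back to unit element variance
make_drift_sheet <- function(n_ch, n_t, smooth_samples) {
  w <- max(1L, smooth_samples)
  x <- matrix(stats::rnorm(n_ch * (n_t + w - 1L)), n_ch, n_t + w - 1L)
  sm <- t(apply(x, 1, function(r) {
    as.numeric(stats::filter(r, rep(1, w) / w, sides = 1))
  }))
  if (n_ch == 1L) sm <- matrix(sm, nrow = 1L)
  sm[, w:(n_t + w - 1L), drop = FALSE] * sqrt(w)
}

# drift processes mirroring the static pattern hierarchy: a category-level
# sheet shared by the category's exemplars plus a smaller exemplar-level
# sheet (relative magnitude exemplar_sd)
make_drift <- function(n_ch, n_categories, n_exemplars, n_t, smooth_samples,
                       exemplar_sd) {
  drifts <- array(0, dim = c(n_ch, n_categories, n_exemplars, n_t))
  for (cc in seq_len(n_categories)) {
    wc <- make_drift_sheet(n_ch, n_t, smooth_samples)
    for (ee in seq_len(n_exemplars)) {
      drifts[, cc, ee, ] <- wc +
        exemplar_sd * make_drift_sheet(n_ch, n_t, smooth_samples)
    }
  }
  drifts
}

# response envelope: 0 before onset, ~20 ms linear ramp already non-zero at
# the onset sample, 1 until stimulus offset, 0 after
response_envelope <- function(times, onset_ms, offset_ms) {
  env <- pmin(1, (times - onset_ms) / 20 + 0.2)
  env[times < onset_ms | times > offset_ms] <- 0
  pmax(env, 0)
}

# unit-variance pink (1/f power) noise, columns independent
pink_noise <- function(n_time, n_series) {
  x <- matrix(stats::rnorm(n_time * n_series), n_time, n_series)
  xf <- stats::mvfft(x)
  freq_idx <- seq_len(n_time) - 1
  freq_idx <- pmin(freq_idx, n_time - freq_idx)  # two-sided spectrum
  w <- ifelse(freq_idx == 0, 0, 1 / sqrt(freq_idx))
  y <- Re(stats::mvfft(xf * w, inverse = TRUE)) / n_time
  y / sqrt(sum(w^2) / n_time)  # analytic unit-variance normalisation
}

#' Noiseless per-trial signal templates for a generator configuration
#'
#' Returns the noise-free signal array underlying one participant's epochs:
#' static category/exemplar patterns (shared by the whole cohort, drawn from
#' `config$seed`), the participant's stimulus-locked pattern drift, region
#' envelopes and lagged coupling. Exposed so that embedded parameters (onset
#' latency, coupling lag) can be verified by direct scans independent of any
#' analysis pipeline.
#'
#' @param config A `generator_config`.
#' @param participant_seed Participant whose drift realisation to build.
#' @return Array `[n_trial_types, n_channels, n_timepoints]` where trial types
#'   run over (category, exemplar) pairs in column-major order, with
#'   attributes `labels` (data.frame) and `times`.
#' @export
signal_templates <- function(config, participant_seed = 1L) {
  mon <- config$montage
  times <- config$times
  n_ch <- nrow(mon)
  n_t <- length(times)
  n_types <- config$n_categories * config$n_exemplars
  labels <- expand.grid(exemplar_id = seq_len(config$n_exemplars),
                        category_id = seq_len(config$n_categories))[, 2:1]
  tmpl <- array(0, dim = c(n_types, n_ch, n_t))
  step <- 1000 / config$sampling_rate
  smooth_samples <- as.integer(round(config$drift_smooth_ms / step))
  region_order <- sort(names(config$signals))
  # per-region noiseless template [type, region channel, time]: envelope times
  # the unit-normalized, slowly drifting category/exemplar pattern
  region_tmpl <- list()
  for (rg in region_order) {
    idx <- which(mon$region == rg)
    if (length(idx) == 0L) next
    # static patterns are cohort-level; the drift realisation is the
    # participant's own (independent across participants)
    set.seed(derive_seed(config$seed, match(rg, region_order)))
    pats <- make_patterns(length(idx), config$n_categories,
                          config$n_exemplars, config$exemplar_sd)
    drift <- if (config$drift_scale > 0) {
      set.seed(derive_seed(config$seed,
                           1000000L + participant_seed * 41L +
                             match(rg, region_order)))
      make_drift(length(idx), config$n_categories, config$n_exemplars, n_t,
                 smooth_samples, config$exemplar_sd)
    } else NULL
    sp <- config$signals[[rg]]
    rt <- array(0, dim = c(n_types, length(idx), n_t))
    if (sp$amplitude > 0) {
      env <- response_envelope(times, sp$onset_ms, config$stimulus_offset_ms)
      for (ty in seq_len(n_types)) {
        v <- matrix(pats[, labels$category_id[ty], labels$exemplar_id[ty]],
                    length(idx), n_t)
        if (!is.null(drift)) {
          v <- v + config$drift_scale *
            drift[, labels$category_id[ty], labels$exemplar_id[ty], ]
        }
        nrm <- sqrt(colSums(v^2))
        rt[ty, , ] <- sp$amplitude * sweep(v, 2, nrm, "/") *
          rep(env, each = length(idx))
      }
    }
    region_tmpl[[rg]] <- rt
    tmpl[, idx, ] <- tmpl[, idx, ] + rt
  }
  cp <- config$coupling
  if (!is.null(cp) && cp$gain > 0 && !is.null(region_tmpl[[cp$source]])) {
    src <- which(mon$region == cp$source)
    tgt <- which(mon$region == cp$target)
    lag_idx <- as.integer(round(cp$lag_ms / step))
    # energy-preserving mixture: the target's own template is attenuated and
    # the source's noiseless template, shifted by the coupling lag, is mixed
    # in; target channel j receives source channel ((j-1) mod n_src)+1
    src_map <- (seq_along(tgt) - 1L) %% length(src) + 1L
    tmpl[, tgt, ] <- sqrt(1 - cp$gain^2) * tmpl[, tgt, , drop = FALSE]
    if (lag_idx < n_t) {
      to <- (lag_idx + 1L):n_t
      from <- seq_len(n_t - lag_idx)
      tmpl[, tgt, to] <- tmpl[, tgt, to] +
        cp$gain * region_tmpl[[cp$source]][, src_map, from, drop = FALSE]
    }
  }
  attr(tmpl, "labels") <- labels
  attr(tmpl, "times") <- times
  tmpl
}

#' Simulate one participant's epoched dataset
#'
#' Generates `n_categories * n_exemplars * n_reps` epochs of multichannel
#' data: the deterministic signal templates from [signal_templates()] plus
#' participant-specific white/pink noise. Fully reproducible from
#' `(config$seed, participant_seed)`.
#'
#' @param config A `generator_config`.
#' @param participant_seed Integer distinguishing this participant's noise.
#' @return An `eeg_epochs` object: list with `data`
#'   (`[trial, channel, time]` array), `times` (ms), `labels`
#'   (data.frame with `category_id`, `exemplar_id`), `montage`,
#'   `sampling_rate` and `participant_id`.
#' @export
simulate_participant <- function(config, participant_seed = 1L) {
  tmpl <- signal_templates(config, participant_seed)
  labels_types <- attr(tmpl, "labels")
  times <- attr(tmpl, "times")
  n_types <- nrow(labels_types)
  n_ch <- dim(tmpl)[2]
  n_t <- dim(tmpl)[3]
  n_trials <- n_types * config$n_reps
  labels <- labels_types[rep(seq_len(n_types), each = config$n_reps), ]
  rownames(labels) <- NULL

  set.seed(derive_seed(config$seed, participant_seed))  # noise stream
  data <- array(0, dim = c(n_trials, n_ch, n_t))
  type_of_trial <- rep(seq_len(n_types), each = config$n_reps)
  for (ty in seq_len(n_types)) {
    rows <- which(type_of_trial == ty)
    data[rows, , ] <- rep(tmpl[ty, , ], each = length(rows))
  }
  ns <- config$noise
  if (ns$white_sd > 0) {
    n_series <- n_trials * n_ch
    white <- matrix(stats::rnorm(n_t * n_series), n_t, n_series)
    if (ns$pink_fraction > 0) {
      pink <- pink_noise(n_t, n_series)
      noise_mat <- sqrt(1 - ns$pink_fraction) * white +
        sqrt(ns$pink_fraction) * pink
    } else {
      noise_mat <- white
    }
    data <- data + ns$white_sd * aperm(array(noise_mat, dim = c(n_t, n_trials, n_ch)),
                                       c(2, 3, 1))
  }
  new_eeg_epochs(data, times, labels, config$montage, config$sampling_rate,
                 participant_id = sprintf("sub-%03d", participant_seed))
}

#' Simulate a cohort of participants
#'
#' @param config A `generator_config`; `config$n_participants` datasets are
#'   generated with derived per-participant seeds and a shared montage.
#' @return A list of `eeg_epochs` objects (class `eeg_cohort`).
#' @export
simulate_cohort <- function(config) {
  if (config$n_participants < 1) stop("n_participants must be >= 1")
  cohort <- lapply(seq_len(config$n_participants), function(p) {
    simulate_participant(config, participant_seed = p)
  })
  class(cohort) <- "eeg_cohort"
  cohort
}

#' Simulate a stationary vector-autoregressive (VAR) series
#'
#' Generates a VAR(p) series with user-supplied coefficient matrices,
#' primarily as a ground-truth fixture for Granger-causality code: the
#' directed structure of the series is known exactly from the coefficients.
#'
#' @param coefficients List of `p` square matrices `A_1 .. A_p`;
#'   `x_t = sum_k A_k x_{t-k} + e_t`. Entry `A[i, j]` is the influence of
#'   series `j` at lag `k` on series `i`.
#' @param noise_sd Innovation standard deviation (iid Gaussian).
#' @param n_samples Number of output samples (after a 200-sample burn-in).
#' @param seed Integer seed.
#' @return Numeric matrix `[n_samples, n_series]`.
#' @export
simulate_var <- function(coefficients, noise_sd = 1, n_samples = 500, seed = 1L) {
  if (!length(coefficients)) stop("need at least one coefficient matrix")
  m <- nrow(coefficients[[1]])
  p <- length(coefficients)
  for (A in coefficients) {
    if (!is.matrix(A) || nrow(A) != m || ncol(A) != m) {
      stop("all coefficient matrices must be square with equal dimension")
    }
  }
  # companion-matrix stationarity check
  comp <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) comp[seq_len(m), (k - 1) * m + seq_len(m)] <- coefficients[[k]]
  if (p > 1) comp[m + seq_len(m * (p - 1)), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("VAR coefficients are non-stationary (spectral radius %.4f >= 1)", rho))
  }
  set.seed(as.integer(seed))
  burn <- 200L
  n_tot <- n_samples + burn
  x <- matrix(0, n_tot, m)
  e <- matrix(stats::rnorm(n_tot * m, sd = noise_sd), n_tot, m)
  for (t in seq_len(n_tot)) {
    acc <- e[t, ]
    for (k in seq_len(min(p, t - 1L))) acc <- acc + coefficients[[k]] %*% x[t - k, ]
    x[t, ] <- acc
  }
  x[burn + seq_len(n_samples), , drop = FALSE]
}
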