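#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix `[channel, sample]`.
#' @param sampling_rate Sampling rate in Hz.
#' @param events data.frame with `sample` (1-based sample index of stimulus
#'   onset), `category_id`, `exemplar_id`.
#' @param montage An `eeg_montage` with one row per channel.
#' @return A `continuous_recording`.
#' @export
continuous_recording <- function(data, sampling_rate, events, montage) {
  stopifnot(is.matrix(data), sampling_rate > 0)
  if (nrow(data) != nrow(montage)) stop("montage/channel count mismatch")
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(data))) {
    stop("event sample indices outside the recording")
  }
  structure(list(data = data, sampling_rate = sampling_rate, events = events,
                 montage = montage),
            class = "continuous_recording")
}

#' Unfold an epoched dataset into a continuous recording
#'
#' Concatenates epochs back-to-back with optional zero padding between them;
#' useful for exercising the preprocessing chain on simulated data.
#'
#' @param epochs An `eeg_epochs`.
#' @param gap_samples Zero samples inserted between consecutive epochs.
#' @return A `continuous_recording` whose events mark each epoch's 0 ms
#'   sample.
#' @export
epochs_to_continuous <- function(epochs, gap_samples = 50L) {
  dims <- dim(epochs$data)
  n_t <- dims[3]
  stride <- n_t + gap_samples
  total <- dims[1] * stride
  dat <- matrix(0, dims[2], total)
  onset_col <- which.min(abs(epochs$times))
  ev_sample <- integer(dims[1])
  for (i in seq_len(dims[1])) {
    cols <- (i - 1L) * stride + seq_len(n_t)
    dat[, cols] <- t(epochs$data[i, , ])
    ev_sample[i] <- cols[onset_col]
  }
  events <- data.frame(sample = ev_sample,
                       category_id = epochs$labels$category_id,
                       exemplar_id = epochs$labels$exemplar_id)
  continuous_recording(dat, epochs$sampling_rate, events, epochs$montage)
}

# zero-phase Butterworth filtering of every channel; the high-pass numerator
# is snapped to its exact binomial form so the DC zero is not lost to
# coefficient rounding (critical for cutoffs far below Nyquist)
butter_filtfilt <- function(data, sampling_rate, cutoff_hz, type, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (sampling_rate / 2), type = type)
  if (type == "high") {
    bf$b <- bf$b[1] * choose(order, 0:order) * (-1)^(0:order)
  }
  t(apply(data, 1, function(ch) {
    mu <- mean(ch)
    signal::filtfilt(bf, ch - mu) + if (type == "low") mu else 0
  }))
}

#' Band-pass filter a continuous recording
#'
#' Applies zero-phase (forward-backward) 4th-order Butterworth high-pass and
#' low-pass filters in sequence. Zero-phase filtering is used so that no
#' latency shift is introduced that could bias onset analyses.
#'
#' @param recording A `continuous_recording`.
#' @param high_pass_hz High-pass cutoff (Hz); removes slow drift.
#' @param low_pass_hz Low-pass cutoff (Hz).
#' @return Filtered `continuous_recording` of identical length.
#' @export
bandpass <- function(recording, high_pass_hz = 0.1, low_pass_hz = 40) {
  fs <- recording$sampling_rate
  if (!(high_pass_hz > 0 && high_pass_hz < low_pass_hz && low_pass_hz < fs / 2)) {
    stop("need 0 < high_pass_hz < low_pass_hz < sampling_rate/2")
  }
  out <- butter_filtfilt(recording$data, fs, high_pass_hz, "high")
  out <- butter_filtfilt(out, fs, low_pass_hz, "low")
  recording$data <- out
  recording
}

#' Downsample a continuous recording by an integer factor
#'
#' Anti-alias filters (zero-phase Butterworth low-pass at 80% of the target
#' Nyquist) and keeps every k-th sample; event indices are rescaled to the
#' new grid.
#'
#' @param recording A `continuous_recording`.
#' @param target_hz Target sampling rate; must divide `sampling_rate`.
#' @return Decimated `continuous_recording`.
#' @export
downsample <- function(recording, target_hz = 250) {
  fs <- recording$sampling_rate
  k <- fs / target_hz
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("sampling_rate (%g) must be an integer multiple of target_hz (%g)",
                 fs, target_hz))
  }
  k <- as.integer(round(k))
  if (k == 1L) return(recording)
  filtered <- butter_filtfilt(recording$data, fs, 0.8 * target_hz / 2, "low")
  keep <- seq(1L, ncol(filtered), by = k)
  recording$data <- filtered[, keep, drop = FALSE]
  recording$sampling_rate <- target_hz
  recording$events$sample <- (recording$events$sample - 1L) %/% k + 1L
  recording
}

#' Re-reference to the average of all channels
#'
#' Subtracts the per-sample mean across channels, so every output sample has
#' zero mean over channels.
#'
#' @param recording A `continuous_recording` with >= 2 channels.
#' @return Re-referenced `continuous_recording`.
#' @export
rereference_average <- function(recording) {
  if (nrow(recording$data) < 2) stop("average reference needs >= 2 channels")
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

#' Detect bad channels (flatline or low correlation)
#'
#' Flags channels that are flat (constant) for at least `flat_seconds`, or
#' whose maximum absolute correlation with any other channel falls below
#' `corr_threshold`.
#'
#' @param recording A `continuous_recording`.
#' @param flat_seconds Minimum flatline duration to flag.
#' @param corr_threshold Minimum acceptable best correlation with the rest
#'   of the montage.
#' @return Character vector of flagged `channel_id`s.
#' @export
detect_bad_channels <- function(recording, flat_seconds = 5,
                                corr_threshold = 0.8) {
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  if (n <= flat_seconds * fs) stop("recording shorter than flat_seconds")
  flat_len <- flat_seconds * fs
  flat <- apply(recording$data, 1, function(ch) {
    r <- rle(diff(ch) == 0)
    any(r$values & (r$lengths + 1L) >= flat_len)
  })
  sds <- apply(recording$data, 1, stats::sd)
  low_corr <- rep(FALSE, nrow(recording$data))
  ok <- sds > 0
  if (sum(ok) >= 2) {
    cm <- abs(stats::cor(t(recording$data[ok, , drop = FALSE])))
    diag(cm) <- 0
    low_corr[ok] <- apply(cm, 1, max) < corr_threshold
  }
  low_corr[!ok] <- TRUE  # zero-variance channels have no usable correlation
  recording$montage$channel_id[flat | low_corr]
}

#' Segment a continuous recording into labelled epochs
#'
#' Cuts a window around every event, on a time grid anchored at the event
#' sample (0 ms), and optionally subtracts the per-trial, per-channel mean of
#' the pre-stimulus samples (baseline correction). Events whose window falls
#' outside the recording are dropped with a message.
#'
#' @param recording A `continuous_recording`.
#' @param window Length-2 ms window around each event.
#' @param baseline_correct Subtract the pre-stimulus mean per trial/channel.
#' @return An `eeg_epochs`.
#' @export
epoch <- function(recording, window = c(-48, 500), baseline_correct = TRUE) {
  fs <- recording$sampling_rate
  times <- time_grid(window, fs)
  offs <- as.integer(round(times * fs / 1000))
  ev <- recording$events
  keep <- ev$sample + min(offs) >= 1 & ev$sample + max(offs) <= ncol(recording$data)
  if (any(!keep)) {
    message(sprintf("epoch(): dropped %d event(s) too close to the recording edge",
                    sum(!keep)))
  }
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) stop("no events with a full epoch window inside the recording")
  n_ch <- nrow(recording$data)
  data <- array(0, dim = c(nrow(ev), n_ch, length(times)))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- recording$data[, ev$sample[i] + offs, drop = FALSE]
  }
  if (baseline_correct) {
    pre <- which(times < 0)
    if (length(pre)) {
      bl <- apply(data[, , pre, drop = FALSE], c(1, 2), mean)
      data <- data - array(bl, dim = dim(data))
    }
  }
  labels <- data.frame(category_id = ev$category_id,
                       exemplar_id = ev$exemplar_id)
  new_eeg_epochs(data, times, labels, recording$montage, fs)
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' @param epochs An `eeg_epochs`.
#' @param abs_threshold Positive amplitude bound; any trial containing a
#'   sample with `|value| > abs_threshold` is removed.
#' @return The dataset with offending trials removed (labels stay aligned).
#' @export
reject_epochs_threshold <- function(epochs, abs_threshold = 100) {
  if (abs_threshold <= 0) stop("abs_threshold must be positive")
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= abs_threshold
  if (!any(keep)) stop("all trials rejected at this threshold")
  if (any(!keep)) {
    message(sprintf("reject_epochs_threshold(): removed %d of %d trial(s)",
                    sum(!keep), length(keep)))
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$labels <- epochs$labels[keep, , drop = FALSE]
  rownames(epochs$labels) <- NULL
  epochs
}
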