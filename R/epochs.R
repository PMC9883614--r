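#' Construct an epoched dataset
#'
#' @param data Numeric array `[trial, channel, time]`.
#' @param times Time axis in ms relative to stimulus onset; strictly
#'   increasing with constant step `1000 / sampling_rate`.
#' @param labels data.frame with per-trial `category_id` and `exemplar_id`.
#' @param montage An `eeg_montage` with one row per channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param participant_id Identifier string.
#' @return An `eeg_epochs` object.
#' @export
new_eeg_epochs <- function(data, times, labels, montage, sampling_rate,
                           participant_id = "sub-001") {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times)) stop("time axis length mismatch")
  if (dim(data)[1] != nrow(labels)) stop("label/trial count mismatch")
  if (dim(data)[2] != nrow(montage)) stop("montage/channel count mismatch")
  step <- 1000 / sampling_rate
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0) || max(abs(d - step)) > 1e-9) {
      stop("times must increase with constant step 1000/sampling_rate")
    }
  }
  structure(list(data = data, times = times, labels = labels,
                 montage = montage, sampling_rate = sampling_rate,
                 participant_id = participant_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s: %d trials x %d channels x %d timepoints (%g-%g ms @ %g Hz)\n",
              x$participant_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$sampling_rate))
  invisible(x)
}

#' Subset an epoched dataset to one region's channels
#' @keywords internal
epochs_region_data <- function(epochs, region, min_channels = 1L) {
  idx <- region_channels(epochs$montage, region, min_channels)
  epochs$data[, idx, , drop = FALSE]
}

#' Trial-averaged response for a set of trials
#'
#' @param epochs An `eeg_epochs`.
#' @param trials Optional trial indices (default all).
#' @return Matrix `[channel, time]`.
#' @export
trial_average <- function(epochs, trials = NULL) {
  d <- epochs$data
  if (!is.null(trials)) d <- d[trials, , , drop = FALSE]
  apply(d, c(2, 3), mean)
}

#' Unique object (category, exemplar) table of a dataset
#' @keywords internal
object_table <- function(epochs) {
  ot <- unique(epochs$labels[, c("category_id", "exemplar_id")])
  ot[order(ot$category_id, ot$exemplar_id), , drop = FALSE]
}

#' Write an epoched dataset to a plain-text container
#'
#' The container is a directory with `data.csv` (long format:
#' `trial, channel, time_index, value`), `trials.csv`
#' (`trial_index, category_id, exemplar_id`), `montage.json` and `meta.json`
#' (`times`, `sampling_rate`, `participant_id`). All files are plain text so
#' containers diff and version cleanly; intended for the small simulated
#' datasets this package works with.
#'
#' @param epochs An `eeg_epochs`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(epochs$data)
  long <- data.frame(
    trial = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    channel = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    time_index = rep(seq_len(dims[3]), each = dims[1] * dims[2]),
    value = as.vector(epochs$data)
  )
  utils::write.csv(long, file.path(dir, "data.csv"), row.names = FALSE)
  trials <- cbind(trial_index = seq_len(dims[1]), epochs$labels)
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(as.data.frame(epochs$montage),
                       file.path(dir, "montage.json"))
  jsonlite::write_json(list(times = epochs$times,
                            sampling_rate = epochs$sampling_rate,
                            participant_id = epochs$participant_id),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an epoched dataset written by [write_epochs()]
#'
#' @param dir Container directory.
#' @return An `eeg_epochs`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  mon <- jsonlite::read_json(file.path(dir, "montage.json"), simplifyVector = TRUE)
  class(mon) <- c("eeg_montage", "data.frame")
  long <- utils::read.csv(file.path(dir, "data.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  n_tr <- max(long$trial); n_ch <- max(long$channel); n_t <- max(long$time_index)
  data <- array(0, dim = c(n_tr, n_ch, n_t))
  data[cbind(long$trial, long$channel, long$time_index)] <- long$value
  labels <- trials[order(trials$trial_index), c("category_id", "exemplar_id")]
  rownames(labels) <- NULL
  new_eeg_epochs(data, meta$times, labels, mon, meta$sampling_rate,
                 meta$participant_id)
}
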