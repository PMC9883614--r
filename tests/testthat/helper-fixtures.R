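# shared fixtures: everything is generated in code at test time

small_montage <- function(dorsal = 6, ventral = 6, occipital = 4, frontal = 4) {
  make_montage(c(dorsal = dorsal, ventral = ventral,
                 occipital = occipital, frontal = frontal))
}

dv_montage <- function(n = 6) make_montage(c(dorsal = n, ventral = n))

# small two-region configuration with explicit onsets; coupling off unless given
dv_config <- function(n_participants = 4, n_reps = 10, n_ch = 6,
                      onset_d = 60, onset_v = 88, amplitude = 0.3,
                      coupling = NULL, noise = list(white_sd = 1,
                                                    pink_fraction = 0.5),
                      seed = 1L, ...) {
  generator_config(
    n_participants = n_participants, n_reps = n_reps,
    montage = dv_montage(n_ch),
    signals = list(dorsal = list(onset_ms = onset_d, amplitude = amplitude),
                   ventral = list(onset_ms = onset_v, amplitude = amplitude)),
    coupling = coupling, noise = noise, seed = seed, ...)
}

default_coupling <- function(lag_ms = 20, gain = 0.7) {
  list(source = "dorsal", target = "ventral", lag_ms = lag_ms, gain = gain)
}

# deterministic epochs with hand-built data for unit tests
manual_epochs <- function(data, times = NULL, sampling_rate = 250,
                          labels = NULL, montage = NULL) {
  dims <- dim(data)
  if (is.null(times)) times <- (seq_len(dims[3]) - 1) * 1000 / sampling_rate
  if (is.null(labels)) {
    labels <- data.frame(category_id = rep(1L, dims[1]),
                         exemplar_id = seq_len(dims[1]))
  }
  if (is.null(montage)) montage <- make_montage(c(dorsal = dims[2]))
  new_eeg_epochs(data, times, labels, montage, sampling_rate)
}
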