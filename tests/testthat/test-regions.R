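# cohort whose regions follow independent latent timecourses: channels within
# a region are the latent plus small noise, so regions are cleanly separable
latent_region_epochs <- function(noise_sd = 0.05, n_regions = 4, n_ch = 4,
                                 n_t = 120, seed = 1) {
  set.seed(seed)
  sizes <- stats::setNames(rep(n_ch, n_regions),
                           c("occipital", "dorsal", "ventral", "frontal")[seq_len(n_regions)])
  mon <- make_montage(sizes)
  latents <- matrix(rnorm(n_regions * n_t), n_regions, n_t)
  data <- array(0, dim = c(2, n_ch * n_regions, n_t))
  for (i in seq_len(nrow(mon))) {
    rg <- match(mon$region[i], names(sizes))
    for (tr in 1:2) {
      data[tr, i, ] <- latents[rg, ] + noise_sd * rnorm(n_t)
    }
  }
  manual_epochs(data, times = (0:(n_t - 1)) * 4, montage = mon,
                labels = data.frame(category_id = c(1L, 1L),
                                    exemplar_id = 1:2))
}

test_that("region-structured data yields perfect clustering purity", {
  ep <- latent_region_epochs()
  rep <- functional_distinctness(list(ep))
  expect_equal(rep$purity, 1.0)
  expect_true(isSymmetric(rep$channel_distance))
  expect_equal(diag(rep$channel_distance), rep(0, 16), ignore_attr = TRUE)
})

test_that("full variance retention reproduces full-space channel distances", {
  ep <- latent_region_epochs(noise_sd = 0.5)
  rep <- functional_distinctness(list(ep), variance_retained = 1.0)
  ta <- t(trial_average(ep))
  centered <- sweep(ta, 2, colMeans(ta))
  expect_lt(max(abs(rep$channel_distance - as.matrix(dist(t(centered))))), 1e-9)
})

test_that("purity on unstructured channels matches its Monte-Carlo chance level", {
  # i.i.d. noise channels carry no region information, so observed purity
  # must match the chance level of the nearest-centroid assignment itself,
  # estimated by permuting the montage's region labels (the assignment is
  # data-adaptive, so its chance level sits above the naive 1/4)
  mon <- make_montage(c(occipital = 4, dorsal = 4, ventral = 4, frontal = 4))
  one_run <- function(s, permute) {
    set.seed(s)
    data <- array(rnorm(2 * 16 * 100), dim = c(2, 16, 100))
    ep <- manual_epochs(data, times = (0:99) * 4, montage = mon,
                        labels = data.frame(category_id = c(1L, 1L),
                                            exemplar_id = 1:2))
    if (permute) {
      perm <- sample(nrow(mon))
      ep$montage$region <- mon$region[perm]
    }
    functional_distinctness(list(ep))$purity
  }
  observed <- vapply(1:10, one_run, numeric(1), permute = FALSE)
  null_mc <- vapply(101:120, one_run, numeric(1), permute = TRUE)
  expect_lt(abs(mean(observed) - mean(null_mc)),
            3 * stats::sd(null_mc) / sqrt(length(null_mc)) +
              3 * stats::sd(observed) / sqrt(length(observed)))
  # and far below the structured-data value of 1
  expect_lt(mean(observed), 0.8)
})

test_that("purity is invariant to channel permutation and global scaling", {
  ep <- latent_region_epochs(noise_sd = 0.3, seed = 4)
  base <- functional_distinctness(list(ep))$purity
  scaled <- ep
  scaled$data <- ep$data * 10
  expect_equal(functional_distinctness(list(scaled))$purity, base)
  perm <- sample(nrow(ep$montage))
  shuffled <- ep
  shuffled$data <- ep$data[, perm, , drop = FALSE]
  shuffled$montage <- ep$montage[perm, , drop = FALSE]
  class(shuffled$montage) <- c("eeg_montage", "data.frame")
  expect_equal(functional_distinctness(list(shuffled))$purity, base)
})

test_that("timecourse SNR matches its closed form and is scale invariant", {
  # trial-averaged signal: constant c plus sinusoid of known sd
  n_t <- 200
  tt <- (0:(n_t - 1)) * 4
  c0 <- 2.5
  sine <- sin(2 * pi * seq_len(n_t) / 25)
  sigma <- stats::sd(sine)
  data <- array(0, dim = c(2, 2, n_t))
  for (tr in 1:2) for (ch in 1:2) data[tr, ch, ] <- c0 + sine
  ep <- manual_epochs(data, times = tt, montage = make_montage(c(dorsal = 2)),
                      labels = data.frame(category_id = c(1L, 1L),
                                          exemplar_id = 1:2))
  expect_equal(snr_timecourse(ep, "dorsal"), c0 / sigma, tolerance = 0.02)
  scaled <- ep
  scaled$data <- ep$data * 7
  expect_equal(snr_timecourse(scaled, "dorsal"),
               snr_timecourse(ep, "dorsal"), tolerance = 1e-12)
  # pure zero-mean noise: near-zero SNR on average over seeds
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    epn <- manual_epochs(array(rnorm(2 * 2 * n_t), dim = c(2, 2, n_t)),
                         times = tt, montage = make_montage(c(dorsal = 2)),
                         labels = data.frame(category_id = c(1L, 1L),
                                             exemplar_id = 1:2))
    snr_timecourse(epn, "dorsal")
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("baseline SNR matches its constructed value and degenerate cases", {
  times <- seq(-48, 300, by = 4)
  n_t <- length(times)
  set.seed(8)
  baseline_noise <- rnorm(sum(times < 0), sd = 0.5)
  m0 <- 3
  data <- array(0, dim = c(2, 2, n_t))
  for (tr in 1:2) for (ch in 1:2) {
    data[tr, ch, times < 0] <- baseline_noise
    data[tr, ch, times >= 0] <- m0
  }
  ep <- manual_epochs(data, times = times, montage = make_montage(c(dorsal = 2)),
                      labels = data.frame(category_id = c(1L, 1L),
                                          exemplar_id = 1:2))
  expect_equal(snr_baseline(ep, "dorsal"), m0 / stats::sd(baseline_noise),
               tolerance = 0.02)
  scaled <- ep
  scaled$data <- ep$data * 10
  expect_equal(snr_baseline(scaled, "dorsal"), snr_baseline(ep, "dorsal"),
               tolerance = 1e-12)
  # identical zero-mean signal in baseline and stimulus windows: SNR ~ 0
  sym <- ep
  wave <- sin(2 * pi * seq_len(n_t) / 8)
  wave <- wave - mean(wave)
  for (tr in 1:2) for (ch in 1:2) sym$data[tr, ch, ] <- wave
  expect_lt(abs(snr_baseline(sym, "dorsal")), 0.2)
})

test_that("matched generation shows no significant SNR difference across regions", {
  cfg <- generator_config(n_participants = 8, n_reps = 10,
                          montage = small_montage(), seed = 21)
  cohort <- simulate_cohort(cfg)
  regions <- c("occipital", "dorsal", "ventral", "frontal")
  vals <- do.call(rbind, lapply(regions, function(rg) {
    data.frame(region = rg,
               snr = vapply(cohort, snr_baseline, numeric(1), region = rg))
  }))
  kt <- stats::kruskal.test(snr ~ factor(region), data = vals)
  expect_gt(kt$p.value, 0.01)
})
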