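# deterministic separable dataset: one distinct channel pattern per category
# switched on after `onset`, no noise
separable_epochs <- function(n_cat = 4, n_ex = 5, n_rep = 2, n_ch = 6,
                             onset = 60, jitter = 0) {
  times <- seq(-48, 500, by = 4)
  labels <- expand.grid(exemplar_id = seq_len(n_ex),
                        category_id = seq_len(n_cat))[, 2:1]
  labels <- labels[rep(seq_len(nrow(labels)), each = n_rep), ]
  rownames(labels) <- NULL
  set.seed(123)
  pats <- matrix(rnorm(n_ch * n_cat), n_ch, n_cat)
  data <- array(0, dim = c(nrow(labels), n_ch, length(times)))
  on <- times >= onset & times <= 300
  for (i in seq_len(nrow(labels))) {
    data[i, , on] <- pats[, labels$category_id[i]] +
      if (jitter > 0) jitter * rnorm(n_ch) else 0
  }
  manual_epochs(data, times = times, montage = make_montage(c(dorsal = n_ch)),
                labels = labels)
}

test_that("linear SVM engine agrees with a reference SVM on separable data", {
  skip_if_not_installed("e1071")
  set.seed(5)
  n <- 60
  centers <- matrix(c(0, 0, 3, 0, 0, 3), 3, 2, byrow = TRUE)
  x <- centers[rep(1:3, each = n), ] + matrix(rnorm(2 * 3 * n, sd = 0.5),
                                              ncol = 2)
  y <- rep(1:3, each = n)
  test_idx <- sample(3 * n, 60)
  ref <- e1071::svm(x[-test_idx, ], factor(y[-test_idx]), kernel = "linear",
                    cost = 1, scale = FALSE)
  ref_pred <- as.integer(as.character(predict(ref, x[test_idx, ])))
  own_pred <- pathwaydyn:::cpp_svm_ovr(x[-test_idx, ],
                                       as.integer(y[-test_idx]),
                                       x[test_idx, ])
  expect_gte(mean(own_pred == ref_pred), 0.95)
})

test_that("noiseless patterns decode perfectly after onset and at chance before", {
  ep <- separable_epochs(onset = 60)
  acc <- decode_timecourse(ep, "dorsal", n_folds = 5)
  tt <- attr(acc, "times")
  expect_equal(attr(acc, "chance"), 0.25)
  expect_true(all(acc[tt >= 60 & tt <= 300] == 1))
  # before onset every feature is 0: accuracy is degenerate-classifier level
  expect_true(all(acc[tt < 60] <= 0.5))
})

test_that("label permutation drives accuracy to chance for 4 and 3 categories", {
  cfg <- dv_config(n_reps = 6, n_ch = 4, seed = 31)
  ep <- simulate_participant(cfg, 1)
  shuffled <- ep
  set.seed(77)
  perm <- sample(nrow(ep$labels))
  shuffled$labels <- ep$labels[perm, ]
  rownames(shuffled$labels) <- NULL
  acc4 <- decode_timecourse(shuffled, "dorsal", n_folds = 10, fold_seed = 1)
  expect_lt(abs(mean(acc4) - 0.25), 0.02)
  acc3 <- decode_timecourse(shuffled, "dorsal", categories = c(2, 3, 4),
                            n_folds = 10, fold_seed = 1)
  expect_equal(attr(acc3, "chance"), 1 / 3)
  expect_lt(abs(mean(acc3) - 1 / 3), 0.025)
})

test_that("decoding generalizes across exemplars only via shared category structure", {
  # exemplar-unique patterns (huge exemplar perturbation, no drift): held-out
  # exemplars cannot be classified above chance
  cfg <- dv_config(n_reps = 8, n_ch = 6, seed = 13, exemplar_sd = 1e6,
                   drift_scale = 0, noise = list(white_sd = 0.2,
                                                 pink_fraction = 0))
  ep <- simulate_participant(cfg, 1)
  acc <- decode_timecourse(ep, "dorsal", n_folds = 10)
  tt <- attr(acc, "times")
  expect_lt(mean(acc[tt >= 100 & tt <= 300]), 0.30)
  # same scale with shared category patterns decodes far above chance
  cfg2 <- dv_config(n_reps = 8, n_ch = 6, seed = 13, exemplar_sd = 0.3,
                    noise = list(white_sd = 0.2, pink_fraction = 0))
  ep2 <- simulate_participant(cfg2, 1)
  acc2 <- decode_timecourse(ep2, "dorsal", n_folds = 10)
  expect_gt(mean(acc2[tt >= 100 & tt <= 300]),
            mean(acc[tt >= 100 & tt <= 300]) + 0.2)
})

test_that("bootstrap CIs flag genuine effects and calibrate at the null", {
  times <- seq(-48, 500, by = 4)
  n_t <- length(times)
  # all participants at 0.5 accuracy from 100 ms on, chance 0.25
  acc <- matrix(0.25, 8, n_t)
  acc[, times >= 100] <- 0.5
  acc <- acc + matrix(rnorm(length(acc), sd = 1e-3), nrow(acc))
  res <- structure(list(accuracy = acc, times = times, chance = 0.25,
                        region = "dorsal"), class = "decoding_result")
  ci <- bootstrap_ci(res, n_boot = 500, seed = 1)
  expect_true(all(ci$above_chance[times >= 100]))
  # pre-effect timepoints sit at chance: only miscoverage-level flagging
  expect_lt(mean(ci$above_chance[times < 100]), 0.15)
  # null calibration: accuracy centered exactly on chance flags only at the
  # one-sided miscoverage rate of the percentile bootstrap (near 2.5%,
  # anti-conservative at small n), averaged over seeds
  frac <- vapply(1:6, function(s) {
    set.seed(s)
    acc0 <- matrix(0.25 + rnorm(20 * n_t, sd = 0.05), 20, n_t)
    res0 <- structure(list(accuracy = acc0, times = times, chance = 0.25,
                           region = "dorsal"), class = "decoding_result")
    mean(bootstrap_ci(res0, n_boot = 400, seed = s + 10)$above_chance)
  }, numeric(1))
  expect_gt(mean(frac), 0)
  expect_lt(mean(frac), 0.10)
})

test_that("bootstrap onsets recover a step function exactly", {
  times <- seq(-48, 500, by = 4)
  acc <- matrix(0.25, 10, length(times))
  acc[, times >= 68] <- 0.5   # steps up at the 68 ms grid point
  res <- structure(list(accuracy = acc, times = times, chance = 0.25,
                        region = "dorsal"), class = "decoding_result")
  on <- bootstrap_onsets(res, n_boot = 200, seed = 4)
  expect_true(all(on$onsets_ms == 68))
  expect_equal(on$median_onset_ms, 68)
})

test_that("the consecutivity rule only reduces detections and nulls stay null", {
  times <- seq(-48, 500, by = 4)
  set.seed(6)
  acc0 <- matrix(0.25 + rnorm(10 * length(times), sd = 0.05), 10)
  res0 <- structure(list(accuracy = acc0, times = times, chance = 0.25,
                         region = "dorsal"), class = "decoding_result")
  on1 <- bootstrap_onsets(res0, n_boot = 300, consecutive = 1, seed = 7)
  on2 <- bootstrap_onsets(res0, n_boot = 300, consecutive = 2, seed = 7)
  det1 <- mean(!is.na(on1$onsets_ms))
  det2 <- mean(!is.na(on2$onsets_ms))
  expect_gte(det1, det2)
  # with the run-length rule, false onsets are rarer than the per-test alpha
  # would suggest for any single timepoint sequence
  expect_lt(det2, 1)
})

test_that("precedence proportions and exact binomial p-values are correct", {
  a <- rep(66, 40); b <- rep(94, 40)
  pr <- precedence_binomial(a, b)
  expect_equal(pr$proportion_a_first, 1)
  expect_lt(pr$p_value, 1e-6)
  # 8 of 10 a-first: exact two-sided binomial p = 2 * P(X >= 8) = 0.109375
  a2 <- c(rep(60, 8), rep(100, 2)); b2 <- rep(80, 10)
  pr2 <- precedence_binomial(a2, b2)
  expect_equal(pr2$proportion_a_first, 0.8)
  expect_equal(pr2$p_value, 0.109375, tolerance = 1e-9)
  # single-sided "none" counts as the other region preceding
  pr3 <- precedence_binomial(c(66, NA), c(NA, 70))
  expect_equal(pr3$k_a_first, 1)
  expect_equal(pr3$n_informative, 2)
  expect_error(precedence_binomial(c(NA, 66), c(NA, 66)), "no informative")
})

test_that("precedence is exactly antisymmetric under region swap", {
  set.seed(9)
  a <- sample(c(seq(60, 120, 4), NA), 200, replace = TRUE)
  b <- sample(c(seq(60, 120, 4), NA), 200, replace = TRUE)
  ok <- !(is.na(a) & is.na(b))
  pr_ab <- precedence_binomial(a, b)
  pr_ba <- precedence_binomial(b, a)
  expect_equal(pr_ab$proportion_a_first + pr_ba$proportion_a_first, 1)
  expect_equal(pr_ab$n_informative, pr_ba$n_informative)
  expect_equal(pr_ab$p_value, pr_ba$p_value)
})

test_that("residualization removes linear mixtures and spares orthogonal signal", {
  cfg <- generator_config(n_participants = 1, n_reps = 4,
                          montage = small_montage(4, 4, 3, 3), seed = 17)
  ep <- simulate_participant(cfg, 1)
  # overwrite one dorsal channel with an exact mixture of non-ROI channels
  rest_idx <- which(!(ep$montage$region %in% c("dorsal", "ventral")))
  mix <- 0.5 * ep$data[, rest_idx[1], ] - 1.25 * ep$data[, rest_idx[4], ]
  d1 <- which(ep$montage$region == "dorsal")[1]
  ep$data[, d1, ] <- mix
  out <- residualize(list(ep), c("dorsal", "ventral"),
                     variance_retained = 1.0)[[1]]
  expect_lt(sqrt(sum(out$data[, d1, ]^2)) / sqrt(sum(mix^2)), 1e-8)
  # untouched dorsal channels keep most of their (independent) signal
  d2 <- which(ep$montage$region == "dorsal")[2]
  kept <- sum(out$data[, d2, ]^2) / sum(ep$data[, d2, ]^2)
  expect_gt(kept, 0.8)
})

test_that("leave-category-out propagates chance levels and pools precedence", {
  cfg <- dv_config(n_participants = 3, n_reps = 4, n_ch = 4, seed = 23)
  cohort <- simulate_cohort(cfg)
  out <- leave_category_out(cohort, c("dorsal", "ventral"), n_resample = 40,
                            n_folds = 4, seed = 3)
  expect_length(out$per_subset, 4)
  expect_length(out$per_subset[["1"]]$onsets_a$onsets_ms, 40)
  expect_true(out$pooled$n_informative <= 4 * 40)
  expect_true(out$pooled$proportion_a_first >= 0 &&
                out$pooled$proportion_a_first <= 1)
})

test_that("channel resampling is deterministic under a fixed seed", {
  cfg <- dv_config(n_participants = 3, n_reps = 4, n_ch = 4, seed = 29)
  cohort <- simulate_cohort(cfg)
  r1 <- channel_resample(cohort, c("dorsal", "ventral"), n_resample = 2,
                         n_folds = 3, seed = 5)
  r2 <- channel_resample(cohort, c("dorsal", "ventral"), n_resample = 2,
                         n_folds = 3, seed = 5)
  expect_identical(r1$onsets_a, r2$onsets_a)
  expect_identical(r1$onsets_b, r2$onsets_b)
})
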