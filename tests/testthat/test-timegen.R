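# tiny RDM series built from known response vectors
vector_epochs <- function(resp, times) {
  # resp: [object, channel, time]; two trials per object so averages are exact
  n_obj <- dim(resp)[1]
  data <- resp[rep(seq_len(n_obj), each = 2), , , drop = FALSE]
  manual_epochs(data, times = times,
                montage = make_montage(c(dorsal = dim(resp)[2])),
                labels = data.frame(
                  category_id = rep(rep(1:2, each = ceiling(n_obj / 2))[seq_len(n_obj)],
                                    each = 2),
                  exemplar_id = rep(seq_len(n_obj), each = 2)))
}

test_that("cosine RDM entries behave as cosine similarities should", {
  times <- c(0, 4)
  resp <- array(0, dim = c(4, 3, 2))
  resp[1, , ] <- c(1, 0, 0)
  resp[2, , ] <- c(1, 0, 0)      # identical to object 1
  resp[3, , ] <- c(0, 1, 0)      # orthogonal
  resp[4, , ] <- c(-1, 0, 0)     # opposite
  ep <- vector_epochs(resp, times)
  rdm <- compute_rdm_series(ep, "dorsal", window = c(0, 4))
  expect_equal(rdm[1, 1, 2], 1)
  expect_equal(rdm[1, 1, 3], 0)
  expect_equal(rdm[1, 1, 4], -1)
  expect_equal(rdm[1, 2, 1], 1)
  expect_true(all(abs(rdm[1, , ] - t(rdm[1, , ])) < 1e-12))
  expect_true(all(diag(rdm[1, , ]) == 1))
})

test_that("default design yields 88 slices of 20 x 20 over -48..300 ms", {
  cfg <- dv_config(n_reps = 2, n_ch = 3, seed = 2)
  ep <- simulate_participant(cfg, 1)
  rdm <- compute_rdm_series(ep, "dorsal")
  expect_equal(dim(rdm), c(88, 20, 20))
  expect_equal(range(attr(rdm, "times")), c(-48, 300))
})

test_that("zero-norm responses raise an error naming object and time", {
  times <- c(0, 4)
  resp <- array(1, dim = c(3, 2, 2))
  resp[2, , 1] <- 0
  ep <- vector_epochs(resp, times)
  expect_error(compute_rdm_series(ep, "dorsal", window = c(0, 4)),
               "object 2 at 0 ms")
})

test_that("time-generalization of a series with itself has unit diagonal", {
  cfg <- dv_config(n_reps = 3, n_ch = 4, seed = 43)
  ep <- simulate_participant(cfg, 1)
  rdm <- compute_rdm_series(ep, "dorsal")
  m <- timegen_matrix(rdm, rdm)
  expect_equal(diag(m), rep(1, 88), tolerance = 1e-12)
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
})

test_that("a delayed copy of a series peaks at the embedded shift", {
  cfg <- dv_config(n_reps = 3, n_ch = 4, seed = 47)
  ep <- simulate_participant(cfg, 1)
  rdm_a <- compute_rdm_series(ep, "dorsal")
  # shift by 5 samples: series B at time t equals A at t - 20 ms
  rdm_b <- rdm_a
  nt <- dim(rdm_a)[1]
  rdm_b[6:nt, , ] <- rdm_a[1:(nt - 5), , ]
  attr(rdm_b, "times") <- attr(rdm_a, "times")
  m <- timegen_matrix(rdm_a, rdm_b)
  interior <- 30:70
  peaks <- vapply(interior, function(i) which.max(m[i, ]) - i, numeric(1))
  expect_equal(stats::median(peaks), 5)
})

test_that("the mirror statistic isolates directed asymmetry exactly", {
  set.seed(51)
  base <- matrix(rnorm(400), 20, 20)
  sym <- (base + t(base)) / 2
  ms0 <- mirror_statistic(list(sym, sym))
  expect_equal(ms0$per_participant, c(0, 0))
  # adding eps to every dorsal-leading cell shifts the statistic by exactly eps
  eps <- 0.05
  shifted <- sym
  shifted[upper.tri(shifted)] <- shifted[upper.tri(shifted)] + eps
  ms1 <- mirror_statistic(list(shifted, shifted))
  expect_equal(ms1$per_participant, c(eps, eps), tolerance = 1e-12)
  # exact antisymmetry under transposition
  m_any <- matrix(rnorm(400), 20, 20)
  msf <- mirror_statistic(list(m_any, shifted))
  msb <- mirror_statistic(list(t(m_any), t(shifted)))
  expect_equal(msf$per_participant, -msb$per_participant)
  expect_equal(msf$t, -msb$t)
  expect_equal(msf$p, msb$p)
})

test_that("correlations are invariant to the similarity/dissimilarity flip", {
  cfg <- dv_config(n_reps = 3, n_ch = 4, seed = 53)
  ep <- simulate_participant(cfg, 1)
  ra <- compute_rdm_series(ep, "dorsal")
  rb <- compute_rdm_series(ep, "ventral")
  m1 <- timegen_matrix(ra, rb)
  ra_d <- ra; rb_d <- rb
  ra_d[] <- 1 - ra[]; rb_d[] <- 1 - rb[]
  m2 <- timegen_matrix(ra_d, rb_d)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rank_and_roll labels, nulls and delays are computed correctly", {
  # analytic null proportion for an 88-point grid rounds to the familiar 0.49
  cfg <- dv_config(n_reps = 2, n_ch = 3, seed = 59)
  ep <- simulate_participant(cfg, 1)
  m <- timegen_matrix(compute_rdm_series(ep, "dorsal"),
                      compute_rdm_series(ep, "ventral"))
  rr <- rank_and_roll(m)
  expect_equal(rr$null_proportion, 87 / 176)
  expect_equal(round(rr$null_proportion, 2), 0.49)
  expect_equal(nrow(rr$ranked), 88 * 88)
  expect_setequal(unique(rr$ranked$label), c("a_leads", "b_leads", "diagonal"))
  # label partition sizes: T diagonal cells, equal split of the rest
  expect_equal(sum(rr$ranked$label == "diagonal"), 88)
  expect_equal(sum(rr$ranked$label == "a_leads"), 88 * 87 / 2)

  # constructed list: top-10 holds 9 a_leads cells with 8 ms delay + 1 diagonal
  mm <- matrix(0, 30, 30)
  attr(mm, "times") <- seq(0, by = 4, length.out = 30)
  for (k in 1:9) mm[k, k + 2] <- 1 - k * 0.01
  mm[15, 15] <- 0.5
  rr2 <- rank_and_roll(mm, window_increment = 10, top_k = 10)
  expect_equal(sum(rr2$top_k_labels == "a_leads"), 9)
  expect_equal(rr2$top_k_mean_delay_ms, 8)

  # symmetric random matrix: rolling proportions hover at the null level
  set.seed(3)
  b <- matrix(rnorm(88 * 88), 88)
  symm <- (b + t(b)) / 2 + 1e-9 * matrix(rnorm(88 * 88), 88)
  attr(symm, "times") <- seq(-48, 300, by = 4)
  rr3 <- rank_and_roll(symm)
  late <- rr3$rolling[rr3$rolling$window_end >= 2000, ]
  expect_lt(max(abs(late$proportion - rr3$null_proportion)), 0.05)
})

test_that("partial correlations equal the residual-regression oracle", {
  cfg <- dv_config(n_reps = 3, n_ch = 4, seed = 61)
  mon <- make_montage(c(dorsal = 4, ventral = 4, frontal = 4))
  cfg <- generator_config(
    n_participants = 1, n_reps = 3, montage = mon,
    signals = list(dorsal = list(onset_ms = 60, amplitude = 0.3),
                   ventral = list(onset_ms = 88, amplitude = 0.3),
                   frontal = list(onset_ms = 100, amplitude = 0.3)),
    coupling = NULL, seed = 61)
  ep <- simulate_participant(cfg, 1)
  ra <- compute_rdm_series(ep, "dorsal")
  rb <- compute_rdm_series(ep, "ventral")
  rc <- compute_rdm_series(ep, "frontal")
  pm <- partial_timegen(ra, rb, rc)
  va <- pathwaydyn:::rdm_vectors(ra)
  vb <- pathwaydyn:::rdm_vectors(rb)
  vc <- pathwaydyn:::rdm_vectors(rc)
  # oracle: correlation of least-squares residuals after regressing on the
  # covariate vector (with intercept)
  oracle <- function(i, j) {
    ra_res <- stats::residuals(stats::lm(va[i, ] ~ vc[i, ]))
    rb_res <- stats::residuals(stats::lm(vb[j, ] ~ vc[i, ]))
    stats::cor(ra_res, rb_res)
  }
  for (idx in list(c(10, 40), c(25, 25), c(60, 30))) {
    expect_equal(pm[idx[1], idx[2]], oracle(idx[1], idx[2]), tolerance = 1e-10)
  }
  # covariate identical to the predictor: partial correlation collapses
  expect_message(pm_self <- partial_timegen(ra, rb, ra), "collinear")
  expect_lt(max(abs(pm_self)), 1e-6)
})
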