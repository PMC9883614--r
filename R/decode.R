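#' Time-resolved category decoding with exemplar-level cross-validation
#'
#' At every timepoint, trains a linear max-margin (SVM) classifier on the
#' multivariate channel pattern of a subset of exemplars from each category
#' and tests on trials of the held-out exemplars, so that above-chance
#' accuracy requires generalization across exemplars rather than memorisation
#' of individual stimuli. With 5 exemplars per category the split is 3
#' train / 2 test; other exemplar counts use a ~60/40 split. Folds are seeded
#' random draws (without replacement) from the joint space of per-category
#' exemplar splits.
#'
#' Features are standardized per fold and timepoint using training-set
#' statistics; the classifier is a linear SVM with fixed regularization
#' `C = 1` trained on single-trial patterns.
#'
#' @param epochs An `eeg_epochs`.
#' @param region Region whose channels form the feature vector.
#' @param categories Category ids to decode (default: all present).
#' @param n_folds Number of cross-validation folds.
#' @param fold_seed Seed for the fold draws.
#' @param C SVM regularization constant.
#' @return Numeric vector of per-timepoint fold-averaged accuracies, with
#'   attributes `times` and `chance`.
#' @export
decode_timecourse <- function(epochs, region, categories = NULL,
                              n_folds = 100, fold_seed = 1L, C = 1) {
  labels <- epochs$labels
  if (is.null(categories)) categories <- sort(unique(labels$category_id))
  if (length(categories) < 2) stop("need at least 2 categories to decode")
  keep <- labels$category_id %in% categories
  labels <- labels[keep, , drop = FALSE]
  idx <- region_channels(epochs$montage, region, min_channels = 2L)
  dat <- epochs$data[keep, idx, , drop = FALSE]

  # per-category exemplar inventory and split sizes
  ex_by_cat <- lapply(categories, function(cc) {
    sort(unique(labels$exemplar_id[labels$category_id == cc]))
  })
  n_ex <- vapply(ex_by_cat, length, integer(1))
  if (any(n_ex < 3)) stop("every category needs >= 3 exemplars for an exemplar split")
  n_test <- pmax(1L, round(0.4 * n_ex))
  n_train <- n_ex - n_test

  # enumerate per-category train subsets and draw joint splits
  subsets <- lapply(seq_along(categories), function(i) {
    utils::combn(ex_by_cat[[i]], n_train[i], simplify = FALSE)
  })
  n_joint <- prod(vapply(subsets, length, integer(1)))
  set.seed(as.integer(fold_seed))
  n_use <- min(n_folds, n_joint)
  joint_ids <- sample.int(n_joint, n_use) - 1
  sizes <- vapply(subsets, length, integer(1))

  n_t <- dim(dat)[3]
  acc <- numeric(n_t)
  y_all <- labels$category_id
  for (f in seq_len(n_use)) {
    id <- joint_ids[f]
    train_trials <- logical(nrow(labels))
    for (i in seq_along(categories)) {
      pick <- subsets[[i]][[(id %% sizes[i]) + 1]]
      id <- id %/% sizes[i]
      train_trials <- train_trials |
        (labels$category_id == categories[i] & labels$exemplar_id %in% pick)
    }
    tr <- aperm(dat[train_trials, , , drop = FALSE], c(2, 1, 3))
    te <- aperm(dat[!train_trials, , , drop = FALSE], c(2, 1, 3))
    acc <- acc + cpp_decode_timepoints(tr, as.integer(y_all[train_trials]),
                                       te, as.integer(y_all[!train_trials]),
                                       C = C)
  }
  acc <- acc / n_use
  attr(acc, "times") <- epochs$times
  attr(acc, "chance") <- 1 / length(categories)
  acc
}

#' Decode a whole cohort
#'
#' Runs [decode_timecourse()] for every participant and collects the
#' per-timepoint accuracies into a `decoding_result`.
#'
#' @inheritParams decode_timecourse
#' @param cohort List of `eeg_epochs` (an `eeg_cohort`).
#' @return A `decoding_result`: list with `accuracy`
#'   (`[participant, timepoint]` matrix), `times`, `chance`, `region`.
#' @export
decode_cohort <- function(cohort, region, categories = NULL, n_folds = 100,
                          fold_seed = 1L, C = 1) {
  accs <- lapply(seq_along(cohort), function(p) {
    decode_timecourse(cohort[[p]], region, categories, n_folds,
                      fold_seed = derive_seed(fold_seed, p), C = C)
  })
  out <- list(accuracy = do.call(rbind, lapply(accs, as.numeric)),
              times = attr(accs[[1]], "times"),
              chance = attr(accs[[1]], "chance"),
              region = region)
  class(out) <- "decoding_result"
  out
}

# bootstrap resample counts matrix [n_boot, n_participants]
resample_counts <- function(n_participants, n_boot) {
  t(replicate(n_boot, tabulate(sample.int(n_participants, n_participants,
                                          replace = TRUE), n_participants)))
}

# resampled per-timepoint means, sds for a [participant x time] matrix
resample_moments <- function(acc, counts) {
  n <- ncol(counts)
  m <- counts %*% acc / n
  s2 <- counts %*% acc^2 / n
  v <- pmax(s2 - m^2, 0) * n / (n - 1)
  list(mean = m, sd = sqrt(v))
}

#' Bootstrap confidence intervals for group decoding accuracy
#'
#' Resamples participants with replacement and builds percentile confidence
#' intervals of the group-mean accuracy at every timepoint; a timepoint is
#' flagged as above chance when the lower CI bound exceeds the chance level.
#'
#' @param result A `decoding_result`.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return data.frame with `time_ms`, `mean`, `lower`, `upper`,
#'   `above_chance`.
#' @export
bootstrap_ci <- function(result, n_boot = 10000, level = 0.95, seed = 1L) {
  acc <- result$accuracy
  if (nrow(acc) < 2) stop("need >= 2 participants for a bootstrap CI")
  if (n_boot < 100) warning("n_boot < 100: confidence intervals will be unstable")
  set.seed(as.integer(seed))
  counts <- resample_counts(nrow(acc), n_boot)
  m <- counts %*% acc / nrow(acc)
  a <- (1 - level) / 2
  lo <- apply(m, 2, stats::quantile, probs = a, names = FALSE)
  hi <- apply(m, 2, stats::quantile, probs = 1 - a, names = FALSE)
  data.frame(time_ms = result$times, mean = colMeans(acc), lower = lo,
             upper = hi, above_chance = lo > result$chance)
}

# first time (>= 0 ms) with a run of >= `consecutive` significant timepoints;
# NA when no such run exists
first_onset <- function(sig, times, consecutive) {
  ok <- times >= 0
  sig <- sig & ok
  if (consecutive > 1) {
    run <- sig
    for (k in seq_len(consecutive - 1)) {
      run <- run & c(sig[-seq_len(k)], rep(FALSE, k))
    }
    sig <- run
  }
  idx <- which(sig)
  if (length(idx)) times[idx[1]] else NA_real_
}

#' Bootstrap distribution of decoding onset latency
#'
#' Resamples participants with replacement; on each resample a one-sided
#' one-sample t-test against chance is run at every timepoint and the onset
#' is the earliest post-stimulus timepoint opening a run of at least
#' `consecutive` significant timepoints (no such run: onset is `NA`).
#' Timepoints with zero between-participant variance are treated as
#' significant iff the resample mean exceeds chance.
#'
#' @param result A `decoding_result` with >= 3 participants.
#' @param n_boot Number of resamples.
#' @param alpha One-sided significance level of the per-timepoint t-test.
#' @param consecutive Required run length of significant timepoints.
#' @param seed Integer seed.
#' @return An `onset_distribution`: list with `onsets_ms` (length `n_boot`,
#'   `NA` = no onset), `median_onset_ms`, `n_boot`, `alpha`, `consecutive`.
#' @export
bootstrap_onsets <- function(result, n_boot = 10000, alpha = 0.05,
                             consecutive = 2, seed = 1L) {
  acc <- result$accuracy
  n <- nrow(acc)
  if (n < 3) stop("need >= 3 participants for the onset t-test")
  set.seed(as.integer(seed))
  counts <- resample_counts(n, n_boot)
  mom <- resample_moments(acc, counts)
  se <- mom$sd / sqrt(n)
  tcrit <- stats::qt(1 - alpha, df = n - 1)
  tstat <- (mom$mean - result$chance) / se
  sig <- tstat > tcrit
  zero_var <- mom$sd < 1e-12
  sig[zero_var] <- mom$mean[zero_var] > result$chance
  onsets <- vapply(seq_len(n_boot), function(b) {
    first_onset(sig[b, ], result$times, consecutive)
  }, numeric(1))
  structure(list(onsets_ms = onsets,
                 median_onset_ms = stats::median(onsets, na.rm = TRUE),
                 n_boot = n_boot, alpha = alpha, consecutive = consecutive),
            class = "onset_distribution")
}

#' Binomial test of onset precedence between two regions
#'
#' Pairs the two onset distributions by resample index and asks how often
#' region A's onset precedes region B's. Ties and resamples where neither
#' region shows an onset are excluded; when only one region has an onset it
#' counts as preceding.
#'
#' @param onsets_a,onsets_b `onset_distribution`s (or numeric vectors with
#'   `NA` for "no onset") of equal length, paired by resample.
#' @return List with `proportion_a_first`, `n_informative`, `k_a_first`,
#'   `p_value` (two-sided exact binomial vs 0.5).
#' @export
precedence_binomial <- function(onsets_a, onsets_b) {
  a <- if (inherits(onsets_a, "onset_distribution")) onsets_a$onsets_ms else onsets_a
  b <- if (inherits(onsets_b, "onset_distribution")) onsets_b$onsets_ms else onsets_b
  if (length(a) != length(b)) stop("onset distributions must be paired (equal length)")
  both_none <- is.na(a) & is.na(b)
  tie <- !is.na(a) & !is.na(b) & a == b
  informative <- !(both_none | tie)
  n <- sum(informative)
  if (n == 0) stop("no informative resamples (all pairs tied or onset-free)")
  a_first <- informative & (is.na(b) | (!is.na(a) & a < b))
  k <- sum(a_first)
  list(proportion_a_first = k / n, n_informative = n, k_a_first = k,
       p_value = stats::binom.test(k, n, p = 0.5)$p.value)
}

# group-level onset on the observed (unresampled) participant sample
group_onset <- function(acc, times, chance, alpha = 0.05, consecutive = 2) {
  n <- nrow(acc)
  m <- colMeans(acc)
  s <- apply(acc, 2, stats::sd)
  tstat <- (m - chance) / (s / sqrt(n))
  sig <- tstat > stats::qt(1 - alpha, df = n - 1)
  sig[s < 1e-12] <- m[s < 1e-12] > chance
  first_onset(sig, times, consecutive)
}

#' Leave-one-category-out decoding control
#'
#' Repeats the decoding + bootstrap-onset pipeline on every 3-category subset
#' obtained by removing one category at a time (chance = 1/3), then pools the
#' paired onset resamples across subsets into one precedence statistic. This
#' checks that an onset asymmetry between two regions is not driven by any
#' single category.
#'
#' @param cohort An `eeg_cohort`.
#' @param region_pair Character vector of two region names, `c(A, B)`.
#' @param n_resample Bootstrap resamples per subset.
#' @param n_folds Cross-validation folds per decode.
#' @param alpha,consecutive Onset-rule parameters (see [bootstrap_onsets()]).
#' @param seed Integer seed.
#' @return List with `per_subset` (per left-out category: onset
#'   distributions and precedence) and `pooled` (precedence over all
#'   subsets' resamples, plus pooled median onsets).
#' @export
leave_category_out <- function(cohort, region_pair, n_resample = 1000,
                               n_folds = 100, alpha = 0.05, consecutive = 2,
                               seed = 1L) {
  cats <- sort(unique(cohort[[1]]$labels$category_id))
  if (length(cats) - 1 < 3) stop("need >= 3 categories remaining after removal")
  per_subset <- list()
  all_a <- numeric(0); all_b <- numeric(0)
  for (i in seq_along(cats)) {
    use <- setdiff(cats, cats[i])
    res_a <- decode_cohort(cohort, region_pair[1], categories = use,
                           n_folds = n_folds, fold_seed = derive_seed(seed, i))
    res_b <- decode_cohort(cohort, region_pair[2], categories = use,
                           n_folds = n_folds, fold_seed = derive_seed(seed, i))
    on_a <- bootstrap_onsets(res_a, n_boot = n_resample, alpha = alpha,
                             consecutive = consecutive,
                             seed = derive_seed(seed, 100 + i))
    on_b <- bootstrap_onsets(res_b, n_boot = n_resample, alpha = alpha,
                             consecutive = consecutive,
                             seed = derive_seed(seed, 200 + i))
    per_subset[[as.character(cats[i])]] <-
      list(left_out = cats[i], onsets_a = on_a, onsets_b = on_b)
    all_a <- c(all_a, on_a$onsets_ms)
    all_b <- c(all_b, on_b$onsets_ms)
  }
  list(per_subset = per_subset,
       pooled = c(precedence_binomial(all_a, all_b),
                  list(median_a_ms = stats::median(all_a, na.rm = TRUE),
                       median_b_ms = stats::median(all_b, na.rm = TRUE))))
}

#' Channel-resampling decoding control
#'
#' Redraws each region's channels with replacement (independently per
#' participant) `n_resample` times, reruns the group decoding analysis on
#' every draw, records the group-level onset for both regions, and tallies
#' how often region A precedes region B. This checks that an onset asymmetry
#' does not hinge on the exact channels selected.
#'
#' @inheritParams leave_category_out
#' @return List with `onsets_a`, `onsets_b` (per resample, ms or `NA`) and
#'   the precedence summary of [precedence_binomial()].
#' @export
channel_resample <- function(cohort, region_pair, n_resample = 1000,
                             n_folds = 100, alpha = 0.05, consecutive = 2,
                             seed = 1L) {
  mon <- cohort[[1]]$montage
  idx_a <- region_channels(mon, region_pair[1], min_channels = 2L)
  idx_b <- region_channels(mon, region_pair[2], min_channels = 2L)
  onsets_a <- numeric(n_resample); onsets_b <- numeric(n_resample)
  for (r in seq_len(n_resample)) {
    set.seed(derive_seed(seed, r))
    for (which_rg in 1:2) {
      idx <- if (which_rg == 1) idx_a else idx_b
      acc <- t(vapply(seq_along(cohort), function(p) {
        pick <- sample(idx, length(idx), replace = TRUE)
        ep <- cohort[[p]]
        sub <- ep
        sub$data <- ep$data[, pick, , drop = FALSE]
        sub$montage <- ep$montage[pick, , drop = FALSE]
        class(sub$montage) <- c("eeg_montage", "data.frame")
        as.numeric(decode_timecourse(sub, region_pair[which_rg],
                                     n_folds = n_folds,
                                     fold_seed = derive_seed(seed, r * 1000 + p)))
      }, numeric(length(cohort[[1]]$times))))
      on <- group_onset(acc, cohort[[1]]$times,
                        1 / length(unique(cohort[[1]]$labels$category_id)),
                        alpha, consecutive)
      if (which_rg == 1) onsets_a[r] <- on else onsets_b[r] <- on
    }
  }
  c(list(onsets_a = onsets_a, onsets_b = onsets_b),
    precedence_binomial(onsets_a, onsets_b))
}

#' Residualize region-of-interest channels against the rest of the montage
#'
#' For each participant, summarises all channels outside the regions of
#' interest by the principal components explaining `variance_retained` of
#' their trialwise (trial-concatenated) variance, then replaces every ROI
#' channel by its least-squares residual after regression on those component
#' timecourses. Used to check that a decoding asymmetry between ROI regions
#' is not inherited from signals elsewhere on the scalp.
#'
#' @param cohort An `eeg_cohort`.
#' @param roi_regions Regions whose channels are residualized.
#' @param variance_retained Fraction of non-ROI variance the retained
#'   components must explain.
#' @return A new `eeg_cohort` with ROI channels replaced by residuals.
#' @export
residualize <- function(cohort, roi_regions = c("dorsal", "ventral"),
                        variance_retained = 0.95) {
  out <- lapply(cohort, function(ep) {
    mon <- ep$montage
    roi <- which(mon$region %in% roi_regions)
    rest <- setdiff(seq_len(nrow(mon)), roi)
    if (!length(rest)) stop("no channels outside the regions of interest")
    dims <- dim(ep$data)
    # rows = trial x time observations, columns = channels
    flat <- matrix(aperm(ep$data, c(1, 3, 2)), nrow = dims[1] * dims[3],
                   ncol = dims[2])
    pc <- stats::prcomp(flat[, rest, drop = FALSE], center = TRUE)
    k <- retained_components(pc$sdev, variance_retained)
    design <- cbind(1, pc$x[, seq_len(k), drop = FALSE])
    qrd <- qr(design)
    resid <- qr.resid(qrd, flat[, roi, drop = FALSE])
    flat[, roi] <- resid
    ep$data <- aperm(array(flat, dim = c(dims[1], dims[3], dims[2])), c(1, 3, 2))
    ep
  })
  class(out) <- "eeg_cohort"
  out
}

# number of leading components whose cumulative variance reaches the target
retained_components <- function(sdev, variance_retained) {
  v <- sdev^2
  cv <- cumsum(v) / sum(v)
  max(1L, which(cv >= variance_retained - 1e-12)[1])
}
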