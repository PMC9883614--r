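#' Concatenated per-object timeseries for one region
#'
#' Builds the input series for Granger-causality analysis: each object's
#' (category x exemplar) trial-averaged channel-by-time response over the
#' stimulus period is concatenated in a fixed object order, with a single
#' separator (an `NA` row) between consecutive objects. Separators mark
#' temporal discontinuities: any autoregression row whose lag window covers a
#' separator is excluded from the model fits, so no prediction ever crosses
#' an object boundary.
#'
#' @param epochs An `eeg_epochs`.
#' @param region Region whose channels form the series.
#' @param window ms window concatenated per object (stimulus onset to
#'   offset).
#' @return Numeric matrix `[time, channel]` with `NA` separator rows, and a
#'   `"separators"` attribute giving their row indices.
#' @export
concat_object_series <- function(epochs, region, window = c(0, 300)) {
  idx <- region_channels(epochs$montage, region)
  tsel <- which(epochs$times >= window[1] & epochs$times <= window[2])
  objs <- object_table(epochs)
  blocks <- lapply(seq_len(nrow(objs)), function(i) {
    rows <- epochs$labels$category_id == objs$category_id[i] &
      epochs$labels$exemplar_id == objs$exemplar_id[i]
    if (!any(rows)) stop("object with no trials")
    ta <- trial_average(epochs, which(rows))
    t(ta[idx, tsel, drop = FALSE])  # time x channel
  })
  n_ch <- length(idx)
  sep <- matrix(NA_real_, 1, n_ch)
  out <- blocks[[1]]
  if (length(blocks) > 1) {
    for (i in 2:length(blocks)) out <- rbind(out, sep, blocks[[i]])
  }
  block_len <- nrow(blocks[[1]])
  attr(out, "separators") <- if (length(blocks) > 1) {
    cumsum(rep(block_len + 1L, length(blocks) - 1L)) - 0L
  } else integer(0)
  out
}

# lagged design rows for order p: row t is usable iff samples t-p..t contain
# no separator
lagged_rows <- function(valid, p) {
  n <- length(valid)
  ok <- valid
  for (k in seq_len(p)) ok <- ok & c(rep(FALSE, k), valid[seq_len(n - k)])
  which(ok)
}

# centered principal-component scores of the non-separator rows, separators
# preserved as NA rows
pca_reduce <- function(series, n_components) {
  valid <- !is.na(series[, 1])
  k <- min(n_components, ncol(series))
  x <- series[valid, , drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE)
  out <- matrix(NA_real_, nrow(series), k)
  out[valid, ] <- pc$x[, seq_len(k), drop = FALSE]
  out
}

# nested VAR fit for one direction at one order; returns log gen. variances
# and degrees of freedom
fit_direction <- function(target, predictor, p) {
  valid <- !is.na(target[, 1])
  rows <- lagged_rows(valid, p)
  m <- ncol(target); kx <- ncol(predictor)
  n <- length(rows)
  n_full_coef <- 1 + m * p + kx * p
  if (n <= n_full_coef + 1) {
    stop(sprintf(paste0("insufficient valid rows (%d) at order %d: need more ",
                        "than %d; lengthen the series"), n, p, n_full_coef + 1))
  }
  own_lags <- do.call(cbind, lapply(seq_len(p), function(k) {
    target[rows - k, , drop = FALSE]
  }))
  pred_lags <- do.call(cbind, lapply(seq_len(p), function(k) {
    predictor[rows - k, , drop = FALSE]
  }))
  y <- target[rows, , drop = FALSE]
  x_r <- cbind(1, own_lags)
  x_f <- cbind(x_r, pred_lags)
  e_r <- stats::.lm.fit(x_r, y)$residuals
  e_f <- stats::.lm.fit(x_f, y)$residuals
  ld_r <- as.numeric(determinant(crossprod(e_r) / n, logarithm = TRUE)$modulus)
  ld_f <- as.numeric(determinant(crossprod(e_f) / n, logarithm = TRUE)$modulus)
  list(n = n, m = m, kx = kx, p = p, logdet_r = ld_r, logdet_f = ld_f,
       bic_full = n * ld_f + log(n) * m * n_full_coef,
       df1 = kx * p, df2 = n - n_full_coef)
}

# F statistic from the generalized-variance ratio; reduces to the classical
# nested-regression F in the univariate case
direction_f <- function(fit) {
  ratio <- exp((fit$logdet_r - fit$logdet_f) / fit$m)
  max(ratio - 1, 0) * fit$df2 / fit$df1
}

#' Multivariate Granger causality between two series
#'
#' Fits nested vector-autoregressions in both directions on the
#' separator-marked series produced by [concat_object_series()]. Each
#' region's channels are first reduced to their top principal components;
#' for every model order up to `max_lag_ms`, a restricted model (the
#' target's own lags) is compared with a full model (plus the predictor's
#' lags), each fit by least squares on rows whose lag window crosses no
#' separator. Each direction uses its best-fitting lag — the order with the
#' strongest Granger F — which is symmetric between the two directions, so
#' the F-difference stays calibrated under the null. The F statistic is
#' formed from the generalized-variance ratio
#' of the restricted and full residual covariances,
#' `F = ((|S_r|/|S_f|)^(1/m) - 1) * df2 / df1`, which reduces to the
#' classical nested-regression F for a univariate target.
#'
#' @param series_x,series_y Matrices `[time, channel]` with aligned `NA`
#'   separator rows (region X and region Y).
#' @param max_lag_ms Maximum VAR order in ms.
#' @param n_components Principal components kept per region (capped at the
#'   channel count).
#' @param sampling_rate Hz; converts `max_lag_ms` to samples.
#' @return A `granger_result`: list with `f_forward` (X -> Y), `f_backward`,
#'   `lag_forward_ms`, `lag_backward_ms`, `f_difference = f_forward -
#'   f_backward`.
#' @export
mvgc <- function(series_x, series_y, max_lag_ms = 50, n_components = 10,
                 sampling_rate = 250) {
  if (nrow(series_x) != nrow(series_y)) stop("series must share length")
  if (!identical(which(is.na(series_x[, 1])), which(is.na(series_y[, 1])))) {
    stop("series must share separator positions")
  }
  max_p <- max(1L, floor(max_lag_ms * sampling_rate / 1000))
  x <- pca_reduce(series_x, n_components)
  y <- pca_reduce(series_y, n_components)
  one_direction <- function(pred, targ) {
    fits <- lapply(seq_len(max_p), function(p) fit_direction(targ, pred, p))
    fs <- vapply(fits, direction_f, numeric(1))
    best <- which.max(fs)  # the direction's best-fitting lag
    list(f = fs[best], lag_ms = best * 1000 / sampling_rate)
  }
  fwd <- one_direction(x, y)
  bwd <- one_direction(y, x)
  structure(list(f_forward = fwd$f, f_backward = bwd$f,
                 lag_forward_ms = fwd$lag_ms, lag_backward_ms = bwd$lag_ms,
                 f_difference = fwd$f - bwd$f),
            class = "granger_result")
}

#' Group-level Granger causality between two regions
#'
#' Runs [concat_object_series()] and [mvgc()] for every participant with
#' region A as predictor (forward = A -> B) and tests the per-participant
#' F-differences against zero with a Wilcoxon signed-rank test. A positive
#' group effect means region A predicts region B beyond B's own history more
#' than the reverse.
#'
#' @param cohort An `eeg_cohort` with >= 6 participants.
#' @param region_pair Character vector `c(A, B)`.
#' @param max_lag_ms,n_components See [mvgc()].
#' @param window Stimulus window passed to [concat_object_series()].
#' @return List with `per_participant` (list of `granger_result`),
#'   `f_difference` (numeric vector), and `group` = list(`W`, `p`, `d`)
#'   where `W` is the signed-rank statistic (sum of positive ranks), `p` the
#'   two-sided p-value and `d = mean/sd` of the differences.
#' @export
group_granger <- function(cohort, region_pair, max_lag_ms = 50,
                          n_components = 10, window = c(0, 300)) {
  if (length(cohort) < 6) stop("need >= 6 participants for the group test")
  per <- lapply(cohort, function(ep) {
    sx <- concat_object_series(ep, region_pair[1], window)
    sy <- concat_object_series(ep, region_pair[2], window)
    mvgc(sx, sy, max_lag_ms, n_components, ep$sampling_rate)
  })
  fd <- vapply(per, `[[`, numeric(1), "f_difference")
  nz <- fd != 0
  if (any(!nz)) {
    message(sprintf("group_granger(): dropped %d zero difference(s) from the signed-rank test",
                    sum(!nz)))
  }
  wt <- stats::wilcox.test(fd[nz], mu = 0, exact = TRUE)
  list(per_participant = per, f_difference = fd,
       group = list(W = unname(wt$statistic), p = wt$p.value,
                    d = mean(fd) / stats::sd(fd)))
}
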