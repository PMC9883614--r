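#' Per-timepoint object similarity matrices (RDM series) for a region
#'
#' At every timepoint in `window`, computes the cosine similarity between the
#' trial-averaged channel response vectors of every pair of objects
#' (category x exemplar), giving one object-by-object similarity matrix per
#' timepoint. With the default 4 x 5 design this is a 20 x 20 matrix per
#' timepoint.
#'
#' @param epochs An `eeg_epochs`.
#' @param region Region whose channels form the response vectors (>= 2
#'   channels).
#' @param window ms window to include.
#' @return An `rdm_series`: array `[timepoint, object, object]` with
#'   attributes `times` and `objects` (the object label table).
#' @export
compute_rdm_series <- function(epochs, region, window = c(-48, 300)) {
  idx <- region_channels(epochs$montage, region, min_channels = 2L)
  tsel <- which(epochs$times >= window[1] & epochs$times <= window[2])
  objs <- object_table(epochs)
  n_obj <- nrow(objs)
  resp <- array(0, dim = c(n_obj, length(idx), length(tsel)))
  for (i in seq_len(n_obj)) {
    rows <- which(epochs$labels$category_id == objs$category_id[i] &
                    epochs$labels$exemplar_id == objs$exemplar_id[i])
    if (!length(rows)) stop("object with no trials")
    resp[i, , ] <- trial_average(epochs, rows)[idx, tsel]
  }
  rdm <- array(0, dim = c(length(tsel), n_obj, n_obj))
  for (t in seq_along(tsel)) {
    v <- resp[, , t, drop = TRUE]
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm < 1e-300)) {
      bad <- which(nrm < 1e-300)[1]
      stop(sprintf("zero-norm response vector for object %d at %g ms",
                   bad, epochs$times[tsel[t]]))
    }
    vn <- v / nrm
    rdm[t, , ] <- tcrossprod(vn)
  }
  attr(rdm, "times") <- epochs$times[tsel]
  attr(rdm, "objects") <- objs
  class(rdm) <- "rdm_series"
  rdm
}

# upper triangle (including the diagonal) of every slice, as rows
rdm_vectors <- function(rdms) {
  n_obj <- dim(rdms)[2]
  ut <- which(upper.tri(matrix(0, n_obj, n_obj), diag = TRUE))
  t(apply(rdms, 1, function(m) m[ut]))
}

# row-standardize for fast pairwise Pearson correlation; zero-variance rows
# flagged
std_rows <- function(v) {
  mu <- rowMeans(v)
  vc <- v - mu
  s <- sqrt(rowSums(vc^2))
  zero <- s < 1e-12
  s[zero] <- 1
  list(x = vc / s, zero = zero)
}

#' Time-generalization matrix between two RDM series
#'
#' Correlates the vectorized upper triangle (including the diagonal) of
#' region A's similarity matrix at every timepoint with region B's at every
#' timepoint. Entry `(t_a, t_b)` is the Pearson correlation between A's
#' representational geometry at `t_a` and B's at `t_b`; region A indexes the
#' rows. Timepoints with zero-variance vectors yield 0 entries (with a
#' message).
#'
#' @param rdms_a,rdms_b `rdm_series` over the same objects and time grid.
#' @return Square correlation matrix `[t_a, t_b]` with a `"times"`
#'   attribute.
#' @export
timegen_matrix <- function(rdms_a, rdms_b) {
  if (!identical(dim(rdms_a), dim(rdms_b))) stop("RDM series dimensions differ")
  va <- std_rows(rdm_vectors(rdms_a))
  vb <- std_rows(rdm_vectors(rdms_b))
  if (any(va$zero) || any(vb$zero)) {
    message("timegen_matrix(): zero-variance RDM vector(s); entries set to 0")
  }
  m <- tcrossprod(va$x, vb$x)
  m[va$zero, ] <- 0
  m[, vb$zero] <- 0
  attr(m, "times") <- attr(rdms_a, "times")
  m
}

#' Mirrored-subtraction directionality statistic
#'
#' For each participant's time-generalization matrix (region A on rows,
#' region B on columns), every cell above the diagonal — where B's timepoint
#' is later than A's — has its mirror cell across the diagonal subtracted
#' from it. The per-participant mean of these differences is positive when
#' region A's geometry predicts region B's future geometry better than the
#' reverse. The per-participant means are tested against zero with a
#' one-sample t-test.
#'
#' @param matrices List of square matrices, one per participant (>= 2).
#' @return List with `per_participant` (mean mirrored difference per
#'   participant), `mean`, `t`, `p` (two-sided), `d = mean/sd`, `df`.
#' @export
mirror_statistic <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) < 2) stop("need >= 2 participants for the t-test")
  per <- vapply(matrices, function(m) {
    if (nrow(m) != ncol(m)) stop("time-generalization matrix must be square")
    up <- upper.tri(m)
    mean(m[up] - t(m)[up])
  }, numeric(1))
  n <- length(per)
  m <- mean(per)
  s <- stats::sd(per)
  if (s < 1e-15) {
    # degenerate spread: the statistic itself is still well defined
    tstat <- if (m == 0) NaN else sign(m) * Inf
    p <- if (m == 0) NaN else 0
  } else {
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  list(per_participant = per, mean = m, t = tstat, p = p,
       d = m / s, df = n - 1)
}

#' Rank-ordered correlations and rolling binomial directionality test
#'
#' Labels every cell of a time-generalization matrix as `a_leads` (region
#' B's timepoint later than region A's: A predicts B's future),
#' `b_leads`, or `diagonal`, sorts cells by correlation (descending, ties
#' broken by earlier region-A then region-B time) and, for every window end
#' `window_increment, 2*window_increment, ...`, tests whether `a_leads`
#' cells make up more of the top correlations than the analytic chance
#' proportion `(T - 1) / (2T)` for a `T x T` matrix (one-sided binomial).
#' Also reports the mean prediction delay (B time minus A time) of the
#' `a_leads` cells among the top `top_k`.
#'
#' @param matrix Square time-generalization matrix with a `"times"`
#'   attribute (ms per axis index).
#' @param window_increment Rolling window step (number of ranked cells).
#' @param top_k Number of top correlations used for the mean delay.
#' @return List with `ranked` (data.frame: `value`, `label`, `time_a_ms`,
#'   `time_b_ms`), `null_proportion`, `rolling` (data.frame: `window_end`,
#'   `k_a_leads`, `proportion`, `p`), `top_k_mean_delay_ms`,
#'   `top_k_labels`.
#' @export
rank_and_roll <- function(matrix, window_increment = 50, top_k = 10) {
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  tt <- attr(matrix, "times")
  n_t <- nrow(matrix)
  if (is.null(tt)) tt <- seq_len(n_t)
  ia <- rep(seq_len(n_t), times = n_t)
  ib <- rep(seq_len(n_t), each = n_t)
  label <- ifelse(ib > ia, "a_leads", ifelse(ib < ia, "b_leads", "diagonal"))
  df <- data.frame(value = as.vector(matrix), label = label,
                   time_a_ms = tt[ia], time_b_ms = tt[ib])
  df <- df[order(-df$value, df$time_a_ms, df$time_b_ms), ]
  rownames(df) <- NULL
  null_prop <- (n_t - 1) / (2 * n_t)
  ends <- seq(window_increment, nrow(df), by = window_increment)
  rolling <- do.call(rbind, lapply(ends, function(w) {
    k <- sum(df$label[seq_len(w)] == "a_leads")
    data.frame(window_end = w, k_a_leads = k, proportion = k / w,
               p = stats::binom.test(k, w, p = null_prop,
                                     alternative = "greater")$p.value)
  }))
  top <- df[seq_len(min(top_k, nrow(df))), ]
  lead_cells <- top$label == "a_leads"
  delay <- if (any(lead_cells)) {
    mean(top$time_b_ms[lead_cells] - top$time_a_ms[lead_cells])
  } else NA_real_
  list(ranked = df, null_proportion = null_prop, rolling = rolling,
       top_k_mean_delay_ms = delay, top_k_labels = top$label)
}

#' Time-generalization with a covariate region partialled out
#'
#' Like [timegen_matrix()], but entry `(t_a, t_b)` is the partial
#' correlation between region A's RDM vector at `t_a` and region B's at
#' `t_b`, controlling for the covariate region's RDM vector at `t_a`. Used
#' to ask whether A's prediction of B's future geometry survives removing a
#' third region's (e.g. frontal) contribution. Entries where the covariate
#' is collinear with either vector are set to 0 with a message.
#'
#' @param rdms_a,rdms_b,rdms_cov `rdm_series` on the same grid.
#' @return Square partial-correlation matrix `[t_a, t_b]` with a `"times"`
#'   attribute.
#' @export
partial_timegen <- function(rdms_a, rdms_b, rdms_cov) {
  if (!identical(dim(rdms_a), dim(rdms_cov))) stop("covariate series grid differs")
  va <- std_rows(rdm_vectors(rdms_a))
  vb <- std_rows(rdm_vectors(rdms_b))
  vc <- std_rows(rdm_vectors(rdms_cov))
  r_ab <- tcrossprod(va$x, vb$x)
  r_ac <- rowSums(va$x * vc$x)           # cor(a_t, cov_t) per timepoint
  r_cb <- tcrossprod(vc$x, vb$x)         # cor(cov_ta, b_tb)
  denom <- sqrt(pmax(1 - r_ac^2, 0)) * sqrt(pmax(1 - r_cb^2, 0))
  num <- r_ab - r_ac * r_cb
  bad <- denom < 1e-8
  denom[bad] <- 1
  out <- num / denom
  if (any(bad)) {
    message("partial_timegen(): collinear covariate cell(s); entries set to 0")
    out[bad] <- 0
  }
  attr(out, "times") <- attr(rdms_a, "times")
  out
}
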