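#' Functional distinctness of region channel groups
#'
#' Tests whether the montage's region assignment is reflected in the data:
#' for each participant, a PCA is run over channels (observations = the
#' timepoints of the trial-averaged response, variables = channels) and the
#' components explaining `variance_retained` of the variance are kept.
#' Pairwise Euclidean distances between the channels' loading vectors
#' (loadings scaled by component standard deviation, so that with all
#' components retained the distances equal full-space distances between
#' centered channel timecourses) are averaged across participants, clustered
#' by average-linkage hierarchical clustering, and the tree is cut at the
#' number of regions. Purity is the fraction of channels whose cluster maps
#' (by nearest region centroid) onto their own montage region.
#'
#' @param cohort An `eeg_cohort` (or single `eeg_epochs`).
#' @param variance_retained Fraction of variance the retained components
#'   must explain.
#' @return A `distinctness_report`: list with `channel_distance`
#'   (symmetric matrix), `hclust` (the average-linkage tree), `cluster`
#'   (channel cluster ids), `cluster_region` (region each cluster maps to)
#'   and `purity`.
#' @export
functional_distinctness <- function(cohort, variance_retained = 0.95) {
  if (inherits(cohort, "eeg_epochs")) cohort <- list(cohort)
  mon <- cohort[[1]]$montage
  regions <- unique(mon$region)
  if (length(regions) < 2) stop("need >= 2 regions in the montage")
  n_ch <- nrow(mon)
  dsum <- matrix(0, n_ch, n_ch)
  for (ep in cohort) {
    ta <- t(trial_average(ep))  # timepoints x channels
    if (nrow(ta) < 2) stop("need >= 2 timepoints for channel PCA")
    pc <- stats::prcomp(ta, center = TRUE)
    k <- retained_components(pc$sdev, variance_retained)
    # rows = channels in retained component space, scaled so distances match
    # the centered full-space channel distances when all components are kept
    load <- pc$rotation[, seq_len(k), drop = FALSE] %*%
      diag(pc$sdev[seq_len(k)] * sqrt(nrow(ta) - 1), k, k)
    dsum <- dsum + as.matrix(stats::dist(load))
  }
  dmat <- dsum / length(cohort)
  rownames(dmat) <- colnames(dmat) <- mon$channel_id
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  cl <- stats::cutree(hc, k = length(regions))
  # embed the averaged distances (classical MDS keeps however many positive
  # dimensions exist) and assign each cluster to the region whose channel
  # centroid is nearest to the cluster centroid
  emb <- suppressWarnings(stats::cmdscale(dmat, k = n_ch - 1L))
  reg_cent <- t(vapply(regions, function(rg) {
    colMeans(emb[mon$region == rg, , drop = FALSE])
  }, numeric(ncol(emb))))
  cluster_region <- vapply(sort(unique(cl)), function(cc) {
    cc_cent <- colMeans(emb[cl == cc, , drop = FALSE])
    d2 <- rowSums(sweep(reg_cent, 2, cc_cent)^2)
    regions[which.min(d2)]
  }, character(1))
  purity <- mean(cluster_region[cl] == mon$region)
  structure(list(channel_distance = dmat, hclust = hc, cluster = cl,
                 cluster_region = cluster_region, purity = purity),
            class = "distinctness_report")
}

#' @export
print.distinctness_report <- function(x, ...) {
  cat(sprintf("<distinctness_report> %d channels, %d clusters, purity %.3f\n",
              nrow(x$channel_distance), length(x$cluster_region), x$purity))
  invisible(x)
}

#' Whole-timecourse signal-to-noise ratio of a region
#'
#' For each region channel, divides the mean of the trial-averaged
#' timecourse by its standard deviation, then averages over the region's
#' channels.
#'
#' @param epochs An `eeg_epochs`.
#' @param region Region name.
#' @return A single SNR value.
#' @export
snr_timecourse <- function(epochs, region) {
  idx <- region_channels(epochs$montage, region)
  ta <- trial_average(epochs)[idx, , drop = FALSE]
  sds <- apply(ta, 1, stats::sd)
  if (any(sds < 1e-300)) stop("zero-variance channel timecourse in region")
  mean(rowMeans(ta) / sds)
}

#' Baseline-referenced signal-to-noise ratio of a region
#'
#' For each region channel, divides the mean of the trial-averaged signal
#' over the stimulus period by the standard deviation of the trial-averaged
#' pre-stimulus baseline, then averages over the region's channels.
#'
#' @param epochs An `eeg_epochs`.
#' @param region Region name.
#' @param stimulus_window ms window of the stimulus period.
#' @return A single SNR value.
#' @export
snr_baseline <- function(epochs, region, stimulus_window = c(0, 300)) {
  idx <- region_channels(epochs$montage, region)
  pre <- epochs$times < 0
  if (!any(pre)) stop("epoch has no pre-stimulus baseline samples")
  stim <- epochs$times >= stimulus_window[1] & epochs$times <= stimulus_window[2]
  ta <- trial_average(epochs)[idx, , drop = FALSE]
  bl_sd <- apply(ta[, pre, drop = FALSE], 1, stats::sd)
  if (any(bl_sd < 1e-300)) stop("zero-variance baseline in region")
  mean(rowMeans(ta[, stim, drop = FALSE]) / bl_sd)
}
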