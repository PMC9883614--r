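#' Build a channel montage with region assignments
#'
#' Creates a montage of named channels grouped into scalp regions. The default
#' layout mirrors the channel-of-interest scheme used throughout the package:
#' 28 dorsal (parietal) channels, 28 ventral (occipitotemporal) channels and
#' 28 frontal channels split evenly between hemispheres, plus 14 occipital
#' channels. Channels within a region are split half left / half right, with
#' any odd remainder placed on the midline, and named
#' `"<region>_<hemisphere>_<k>"`.
#'
#' @param region_sizes Named integer vector mapping region name to channel
#'   count. Regions must be unique; counts must be non-negative. Recognised
#'   region names are `"occipital"`, `"dorsal"`, `"ventral"`, `"frontal"` and
#'   `"other"`, but arbitrary names are allowed.
#' @return An object of class `eeg_montage`: a data.frame with columns
#'   `channel_id`, `region` and `hemisphere` (`"left"`, `"right"` or
#'   `"midline"`).
#' @examples
#' mon <- make_montage()
#' table(mon$region)
#' @export
make_montage <- function(region_sizes = c(occipital = 14, dorsal = 28,
                                          ventral = 28, frontal = 28)) {
  if (is.null(names(region_sizes)) || any(names(region_sizes) == "")) {
    stop("`region_sizes` must be a named vector")
  }
  if (anyDuplicated(names(region_sizes))) {
    stop("duplicate region name in `region_sizes`")
  }
  if (any(region_sizes < 0)) stop("region channel counts must be >= 0")
  rows <- lapply(names(region_sizes), function(region) {
    n <- region_sizes[[region]]
    if (n == 0L) return(NULL)
    n_side <- n %/% 2L
    hemi <- c(rep("left", n_side), rep("right", n_side),
              rep("midline", n - 2L * n_side))
    data.frame(
      channel_id = sprintf("%s_%s_%d", region, substr(hemi, 1L, 1L), seq_len(n)),
      region = region,
      hemisphere = hemi,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(channel_id = character(), region = character(),
                      hemisphere = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$channel_id))
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Channel indices of a region
#'
#' @param montage An `eeg_montage`.
#' @param region Region name.
#' @param min_channels Minimum number of channels required (error below).
#' @return Integer indices into the montage rows.
#' @keywords internal
region_channels <- function(montage, region, min_channels = 1L) {
  idx <- which(montage$region == region)
  if (length(idx) < min_channels) {
    stop(sprintf("region '%s' has %d channel(s) in the montage; >= %d required",
                 region, length(idx), min_channels))
  }
  idx
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$region)), table(x$region)),
                    collapse = ", ")))
  invisible(x)
}
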