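#' Assemble a pipeline configuration
#'
#' Bundles the generator settings and per-stage parameters for
#' [run_pipeline()]. Unknown stage names or parameter-block keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param generator A `generator_config` (its `seed` is overridden by
#'   `master_seed`).
#' @param stages Character vector of stages to run, in order, from
#'   `"simulate"`, `"regions"`, `"decode"`, `"granger"`, `"timegen"`.
#'   Every analysis stage requires `"simulate"`.
#' @param region_pair The two regions compared by the analysis stages.
#' @param decode Parameter block: `n_folds`, `n_boot`, `alpha`,
#'   `consecutive`.
#' @param granger Parameter block: `max_lag_ms`, `n_components`.
#' @param timegen Parameter block: `window`, `window_increment`, `top_k`,
#'   `covariate` (region name or `NULL`).
#' @param output_dir Directory for stage outputs and the manifest.
#' @param master_seed Integer seed from which every stage seed derives.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            stages = c("simulate", "regions", "decode",
                                       "granger", "timegen"),
                            region_pair = c("dorsal", "ventral"),
                            decode = list(),
                            granger = list(),
                            timegen = list(),
                            output_dir = tempfile("pathwaydyn_run_"),
                            master_seed = 1L) {
  known <- c("simulate", "regions", "decode", "granger", "timegen")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop(sprintf("unknown stage(s) %s; valid stages: %s",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  check_block <- function(block, valid, name) {
    extra <- setdiff(names(block), valid)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in %s block: %s; valid keys: %s", name,
                   paste(extra, collapse = ", "), paste(valid, collapse = ", ")))
    }
    block
  }
  decode <- utils::modifyList(list(n_folds = 100, n_boot = 1000, alpha = 0.05,
                                   consecutive = 2),
                              check_block(decode, c("n_folds", "n_boot",
                                                    "alpha", "consecutive"),
                                          "decode"))
  granger <- utils::modifyList(list(max_lag_ms = 50, n_components = 10),
                               check_block(granger, c("max_lag_ms",
                                                      "n_components"),
                                           "granger"))
  timegen <- utils::modifyList(list(window = c(-48, 300),
                                    window_increment = 50, top_k = 10,
                                    covariate = NULL),
                               check_block(timegen, c("window",
                                                      "window_increment",
                                                      "top_k", "covariate"),
                                           "timegen"))
  for (rg in region_pair) region_channels(generator$montage, rg, 2L)
  if (master_seed < 0) stop("master_seed must be a non-negative integer")
  generator$seed <- as.integer(master_seed)
  structure(list(generator = generator, stages = stages,
                 region_pair = region_pair, decode = decode,
                 granger = granger, timegen = timegen,
                 output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate a cohort, validate region
#' distinctness and SNR, time-resolved decoding with bootstrap onsets and
#' precedence, group Granger causality, time-generalized RSA — writing each
#' stage's outputs (CSV for curves and matrices, JSON for statistics) plus a
#' manifest recording the parameter snapshot, derived seeds and output file
#' hashes. Running the same configuration twice writes byte-identical
#' results.
#'
#' @param config A `pipeline_config`.
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  cohort <- NULL
  gen <- config$generator
  rp <- config$region_pair
  write_json_out <- function(x, name) {
    path <- file.path(config$output_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  }
  need_cohort <- function(stage) {
    if (is.null(cohort)) {
      stop(sprintf("stage '%s' requires the 'simulate' stage to run first", stage))
    }
  }
  for (stage in config$stages) {
    if (stage == "simulate") {
      cohort <- simulate_cohort(gen)
      outputs$simulate <- write_json_out(
        list(n_participants = length(cohort),
             n_trials = dim(cohort[[1]]$data)[1],
             n_channels = dim(cohort[[1]]$data)[2],
             n_timepoints = dim(cohort[[1]]$data)[3]),
        "simulate.json")
    } else if (stage == "regions") {
      need_cohort(stage)
      fd <- functional_distinctness(cohort)
      snr <- lapply(unique(gen$montage$region), function(rg) {
        list(region = rg,
             snr_timecourse = mean(vapply(cohort, snr_timecourse, numeric(1),
                                          region = rg)),
             snr_baseline = mean(vapply(cohort, snr_baseline, numeric(1),
                                        region = rg)))
      })
      dist_path <- file.path(config$output_dir, "channel_distance.csv")
      utils::write.csv(fd$channel_distance, dist_path)
      outputs$regions <- c(write_json_out(list(purity = fd$purity, snr = snr),
                                          "regions.json"), dist_path)
    } else if (stage == "decode") {
      need_cohort(stage)
      res <- lapply(rp, function(rg) {
        decode_cohort(cohort, rg, n_folds = config$decode$n_folds,
                      fold_seed = derive_seed(config$master_seed, match(rg, rp)))
      })
      # one shared bootstrap seed: resamples draw the same participants for
      # both regions, pairing the precedence comparison
      ons <- lapply(seq_along(rp), function(i) {
        bootstrap_onsets(res[[i]], n_boot = config$decode$n_boot,
                         alpha = config$decode$alpha,
                         consecutive = config$decode$consecutive,
                         seed = derive_seed(config$master_seed, 10))
      })
      prec <- precedence_binomial(ons[[1]], ons[[2]])
      acc <- do.call(rbind, lapply(seq_along(rp), function(i) {
        data.frame(region = rp[i], time_ms = res[[i]]$times,
                   accuracy = colMeans(res[[i]]$accuracy))
      }))
      acc_path <- file.path(config$output_dir, "accuracy.csv")
      utils::write.csv(acc, acc_path, row.names = FALSE)
      onset_path <- file.path(config$output_dir, "onsets.csv")
      utils::write.csv(data.frame(resample = seq_len(config$decode$n_boot),
                                  onset_a_ms = ons[[1]]$onsets_ms,
                                  onset_b_ms = ons[[2]]$onsets_ms),
                       onset_path, row.names = FALSE)
      outputs$decode <- c(write_json_out(
        list(chance = res[[1]]$chance,
             median_onset_a_ms = ons[[1]]$median_onset_ms,
             median_onset_b_ms = ons[[2]]$median_onset_ms,
             precedence = prec), "decode.json"), acc_path, onset_path)
    } else if (stage == "granger") {
      need_cohort(stage)
      gg <- group_granger(cohort, rp, max_lag_ms = config$granger$max_lag_ms,
                          n_components = config$granger$n_components)
      outputs$granger <- write_json_out(
        list(f_difference = gg$f_difference, group = gg$group), "granger.json")
    } else if (stage == "timegen") {
      need_cohort(stage)
      tg <- config$timegen
      rdms_a <- lapply(cohort, compute_rdm_series, region = rp[1],
                       window = tg$window)
      rdms_b <- lapply(cohort, compute_rdm_series, region = rp[2],
                       window = tg$window)
      mats <- Map(timegen_matrix, rdms_a, rdms_b)
      ms <- mirror_statistic(mats)
      avg <- Reduce(`+`, mats) / length(mats)
      attr(avg, "times") <- attr(mats[[1]], "times")
      rr <- rank_and_roll(avg, window_increment = tg$window_increment,
                          top_k = tg$top_k)
      mat_path <- file.path(config$output_dir, "timegen_matrix.csv")
      utils::write.csv(avg, mat_path, row.names = FALSE)
      out <- list(mirror = ms[c("mean", "t", "p", "d", "df")],
                  null_proportion = rr$null_proportion,
                  top_k_mean_delay_ms = rr$top_k_mean_delay_ms,
                  rolling = rr$rolling)
      if (!is.null(tg$covariate)) {
        rdms_c <- lapply(cohort, compute_rdm_series, region = tg$covariate,
                         window = tg$window)
        pm <- Map(partial_timegen, rdms_a, rdms_b, rdms_c)
        out$partial_mirror <- mirror_statistic(pm)[c("mean", "t", "p", "d", "df")]
      }
      outputs$timegen <- c(write_json_out(out, "timegen.json"), mat_path)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("pathwaydyn")),
    master_seed = config$master_seed,
    stages = config$stages,
    region_pair = rp,
    parameters = list(
      generator = gen[c("n_participants", "n_categories", "n_exemplars",
                        "n_reps", "sampling_rate", "epoch_window", "signals",
                        "coupling", "noise", "exemplar_sd", "seed")],
      decode = config$decode, granger = config$granger,
      timegen = config$timegen),
    outputs = lapply(outputs, function(paths) {
      lapply(paths, function(p) list(file = basename(p),
                                     md5 = unname(tools::md5sum(p))))
    }))
  path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Human-readable report of a pipeline run
#'
#' @param output_dir Directory holding a `manifest.json` and stage outputs
#'   written by [run_pipeline()].
#' @return The report lines, invisibly (also printed).
#' @export
summarize_pipeline <- function(output_dir) {
  manifest_path <- file.path(output_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", output_dir)
  manifest <- tryCatch(jsonlite::read_json(manifest_path),
                       error = function(e) {
                         stop("could not parse ", manifest_path, ": ",
                              conditionMessage(e))
                       })
  lines <- c(sprintf("pathwaydyn pipeline run (master seed %s)",
                     manifest$master_seed),
             sprintf("regions: %s vs %s", manifest$region_pair[[1]],
                     manifest$region_pair[[2]]))
  read_stage <- function(name) {
    p <- file.path(output_dir, name)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }
  dec <- read_stage("decode.json")
  lines <- c(lines, "-- decoding --",
             if (is.null(dec)) "  (absent)" else c(
               sprintf("  median onset A: %s ms, B: %s ms",
                       dec$median_onset_a_ms, dec$median_onset_b_ms),
               sprintf("  A-first proportion %.3f (binomial p = %.3g)",
                       dec$precedence$proportion_a_first, dec$precedence$p_value)))
  gg <- read_stage("granger.json")
  lines <- c(lines, "-- granger --",
             if (is.null(gg)) "  (absent)" else
               sprintf("  W = %g, p = %.3g, d = %.2f, mean F-diff = %.4f",
                       gg$group$W, gg$group$p, gg$group$d,
                       mean(unlist(gg$f_difference))))
  tg <- read_stage("timegen.json")
  lines <- c(lines, "-- timegen --",
             if (is.null(tg)) "  (absent)" else
               sprintf("  mirror t = %.2f, p = %.3g, d = %.2f; top-k delay %.1f ms",
                       tg$mirror$t, tg$mirror$p, tg$mirror$d,
                       tg$top_k_mean_delay_ms))
  cat(lines, sep = "\n")
  invisible(lines)
}
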