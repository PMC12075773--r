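## Cohort orchestration: run every analysis stage over a set of synthetic
## "animals" (independent generator seeds) and collect a long-format summary
## table ready for external statistics.

#' Run the full analysis pipeline over a synthetic cohort
#'
#' For each of `n_animals` independent generator seeds (derived from
#' `config$seed`), simulates a recording, conditions it
#' ([lowpass_downsample()] to 200 Hz when sampled faster), epochs it around
#' the stimuli, and computes per condition and region pair: the
#' baseline-subtracted Welch spectrum peak, wPLI and wSMI sliding-window
#' time courses (summarized as the mean over `summary_window`), and — per
#' odorant pair — the band-power co-information contrast.  Optionally runs
#' multivariate spectral decoding per animal and a group-level cluster
#' permutation test.
#'
#' @param config a [synth_config()] describing one animal; each animal uses
#'   a derived seed.
#' @param n_animals number of independent simulated subjects (default 12).
#' @param epoch_window seconds pair around the stimulus.
#' @param summary_window seconds pair for window means (default 1--5 s).
#' @param measures subset of `c("spectra", "coherence", "wpli", "wsmi",
#'   "coinfo")`.
#' @param step_s sliding-window step for the connectivity time courses
#'   (coarser than the 2 ms chart default to keep cohort runs tractable).
#' @param decode_freqs Hz grid for decoding, or `NULL` to skip decoding.
#' @param decode_decim time decimation for the decoding features.
#' @param n_perm permutations for the group cluster test.
#' @param out_dir optional directory; when given, the summary table and the
#'   cluster table are written there as CSV.
#' @return An `olf_pipeline_result`: list with `summary` (long data.frame:
#'   animal, seed, measure, pair, condition, value), `cluster_test` (or
#'   `NULL`), `animal_seeds`, `config`.
#' @export
run_pipeline <- function(config, n_animals = 12,
                         epoch_window = c(-10, 10),
                         summary_window = c(1, 5),
                         measures = c("spectra", "coherence", "wpli", "wsmi",
                                      "coinfo"),
                         step_s = 0.05,
                         decode_freqs = NULL, decode_decim = 20,
                         n_perm = 500, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  measures <- match.arg(measures, several.ok = TRUE)
  animal_seeds <- derive_seeds(config$seed, n_animals)
  regions <- config$regions
  pairs <- utils::combn(seq_along(regions), 2)
  odor_classes <- setdiff(config$classes, config$control_class)
  rows <- list()
  auc_maps <- list()
  add_row <- function(animal, seed, measure, pair, condition, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      animal = animal, seed = seed, measure = measure, pair = pair,
      condition = condition, value = value, stringsAsFactors = FALSE)
  }

  for (a in seq_len(n_animals)) {
    cfg_a <- config
    cfg_a$seed <- animal_seeds[a]
    rec <- generate_recording(cfg_a)
    if (rec$fs > 250) rec <- lowpass_downsample(rec, 50, 3, 200)
    ep <- epoch(rec, epoch_window, baseline = c(epoch_window[1], 0))

    if ("spectra" %in% measures) {
      for (r in seq_along(regions)) for (cls in config$classes) {
        tr <- ep$labels == cls
        spec <- baseline_subtract(
          welch_spectrum(ep, r, interval = "post", trials = tr),
          welch_spectrum(ep, r, interval = "pre", trials = tr))
        band <- spec$freqs >= 2 & spec$freqs <= 20
        add_row(a, animal_seeds[a], "peak_freq", regions[r], cls,
                spec$freqs[band][which.max(spec$power[band])])
        add_row(a, animal_seeds[a], "peak_power", regions[r], cls,
                max(spec$power[band]))
      }
    }
    for (p in seq_len(ncol(pairs))) {
      pr <- pairs[, p]
      pair_name <- paste(regions[pr], collapse = "-")
      if ("coherence" %in% measures) {
        for (cls in config$classes) {
          cs <- coherence_spectrum(epoch_subset(ep, ep$labels == cls), pr,
                                   interval = "post", baseline_subtract = TRUE)
          sel <- cs$freqs >= config$evoked_band[1] & cs$freqs <= config$evoked_band[2]
          add_row(a, animal_seeds[a], "coherence", pair_name, cls,
                  max(cs$coh[sel]))
        }
      }
      if ("wpli" %in% measures) {
        for (cls in config$classes) {
          tc <- wpli_timecourse(epoch_subset(ep, ep$labels == cls), pr,
                                step_s = step_s)
          add_row(a, animal_seeds[a], "wpli", pair_name, cls,
                  timecourse_mean(tc, summary_window, "raw"))
        }
      }
      if ("wsmi" %in% measures) {
        for (cls in config$classes) {
          tc <- wsmi_timecourse(epoch_subset(ep, ep$labels == cls), pr,
                                step_s = step_s)
          add_row(a, animal_seeds[a], "wsmi", pair_name, cls,
                  timecourse_mean(tc, summary_window, "raw"))
        }
      }
      if ("coinfo" %in% measures && length(odor_classes) >= 2) {
        cps <- utils::combn(odor_classes, 2)
        for (cp in seq_len(ncol(cps))) {
          res <- coinfo_pipeline(ep, pr, cps[, cp], post = summary_window)
          add_row(a, animal_seeds[a], "coinfo_post", pair_name,
                  paste(cps[, cp], collapse = "-"), res$post_mean)
          add_row(a, animal_seeds[a], "coinfo_contrast", pair_name,
                  paste(cps[, cp], collapse = "-"), res$contrast)
        }
      }
    }
    if (!is.null(decode_freqs)) {
      keep <- balance_by_undersampling(ep$labels, seed = animal_seeds[a])
      ft <- tf_features(epoch_subset(ep, keep), freqs = decode_freqs,
                        window = c(0, epoch_window[2]),
                        time_decim = decode_decim)
      dmap <- decode_multiclass(ft, seed = animal_seeds[a])
      auc_maps[[a]] <- dmap$auc
      add_row(a, animal_seeds[a], "auc_mean", "all",
              "multiclass", mean(dmap$auc))
    }
  }
  summary <- do.call(rbind, rows)
  ct <- NULL
  if (!is.null(decode_freqs))
    ct <- cluster_permutation_test(auc_maps, chance = 0.5, n_perm = n_perm,
                                   seed = config$seed)
  out <- list(summary = summary, cluster_test = ct,
              animal_seeds = animal_seeds, config = config)
  class(out) <- "olf_pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(ct))
      utils::write.csv(ct$clusters, file.path(out_dir, "clusters.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(n_animals = n_animals,
                              animal_seeds = animal_seeds,
                              master_seed = config$seed),
                         file.path(out_dir, "run.json"), auto_unbox = TRUE)
  }
  out
}

#' @export
print.olf_pipeline_result <- function(x, ...) {
  cat(sprintf("<olf_pipeline_result> %d animals, %d summary rows\n",
              length(x$animal_seeds), nrow(x$summary)))
  if (!is.null(x$cluster_test)) print(x$cluster_test)
  invisible(x)
}

#' Export the per-animal summary table
#'
#' Extracts (and optionally writes) the long-format table of window means —
#' one row per animal, measure, region pair and condition — the shape
#' expected by external statistics packages for group-level tests.
#'
#' @param result an `olf_pipeline_result`.
#' @param path optional CSV path.
#' @param measures optional measure filter.
#' @return The (filtered) summary data.frame, invisibly when writing.
#' @export
export_summary <- function(result, path = NULL, measures = NULL) {
  stopifnot(inherits(result, "olf_pipeline_result"))
  s <- result$summary
  if (!is.null(measures)) s <- s[s$measure %in% measures, ]
  if (any(!is.finite(s$value))) stopf("summary contains non-finite values")
  if (anyDuplicated(s[, c("animal", "measure", "pair", "condition")]))
    stopf("duplicated summary keys")
  if (!is.null(path)) {
    utils::write.csv(s, path, row.names = FALSE)
    return(invisible(s))
  }
  s
}
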