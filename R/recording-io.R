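## Plain-text serialization of recordings and epoch sets: a delimited sample
## matrix (one column per channel) plus a JSON sidecar carrying the sampling
## rate, channel labels and event table.

#' Write / read a recording as delimited text plus JSON sidecar
#'
#' `write_recording()` stores the sample matrix as tab-separated text (one
#' column per channel, one row per sample) and the metadata (`fs`,
#' `channel_labels`, `events`, `sweep_samples`, `seed`) in `<path>.json`.
#' `read_recording()` restores an identical `lfp_recording`.
#'
#' @param rec an `lfp_recording`.
#' @param path file path for the sample matrix; the sidecar is `<path>.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `lfp_recording`.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  utils::write.table(t(rec$data), path, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_labels, quote = FALSE)
  meta <- list(fs = rec$fs, channel_labels = rec$channel_labels,
               events = rec$events, sweep_samples = rec$sweep_samples,
               seed = rec$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rec <- list(data = t(m), fs = meta$fs, channel_labels = meta$channel_labels,
              events = as.data.frame(meta$events),
              sweep_samples = meta$sweep_samples, seed = meta$seed,
              config = NULL)
  rownames(rec$data) <- meta$channel_labels
  class(rec) <- "lfp_recording"
  validate_recording(rec)
  rec
}
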