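## Magnitude-squared coherence between region pairs from Welch cross- and
## auto-spectra, with optional pre-stimulus baseline subtraction.

#' Coherence spectrum between two channels
#'
#' Magnitude-squared coherence
#' `C_xy(f) = |<P_x* P_y>|^2 / (<|P_x|^2> <|P_y|^2>)` with Welch
#' cross/auto-spectral estimators (Hann taper, default 500-sample windows,
#' 350-sample overlap), segments pooled across all trials before averaging.
#' With `baseline_subtract = TRUE` the coherence of the pre-stimulus interval
#' is subtracted, giving values in \[-1, 1\].
#'
#' @param ep an `epoch_set`.
#' @param pair two channel indices or labels.
#' @param window,overlap Welch segment length and overlap in samples.
#' @param interval `"pre"`, `"post"`, or a seconds pair.
#' @param baseline_subtract subtract the `"pre"`-interval coherence?
#' @return A `coherence_spectrum`: list with `freqs`, `coh`, `pair`,
#'   `baseline_subtracted`, `n_segments`.
#' @export
coherence_spectrum <- function(ep, pair = c(1, 2), window = 500, overlap = 350,
                               interval = "post", baseline_subtract = FALSE) {
  validate_epochs(ep)
  if (is.character(pair)) pair <- match(pair, ep$channel_labels)
  if (length(pair) != 2 || pair[1] == pair[2])
    stopf("pair must name two distinct channels")
  coh_of <- function(interval) {
    idx <- interval_index(ep, resolve_interval(ep, interval))
    n_trials <- dim(ep$data)[1]
    sxy <- sxx <- syy <- NULL; n_seg <- 0
    for (i in seq_len(n_trials)) {
      x <- ep$data[i, pair[1], idx]; y <- ep$data[i, pair[2], idx]
      cxy <- welch_xspec(x, y, ep$fs, window, overlap)
      cxx <- welch_xspec(x, NULL, ep$fs, window, overlap)
      cyy <- welch_xspec(y, NULL, ep$fs, window, overlap)
      if (is.null(sxy)) { sxy <- cxy$spec; sxx <- cxx$spec; syy <- cyy$spec }
      else { sxy <- sxy + cxy$spec; sxx <- sxx + cxx$spec; syy <- syy + cyy$spec }
      n_seg <- n_seg + cxy$n_segments
    }
    if (n_seg < 2)
      stopf("coherence needs >= 2 Welch segments (one segment is identically 1)")
    list(freqs = cxy$freqs, coh = Mod(sxy)^2 / (Re(sxx) * Re(syy)),
         n_segments = n_seg)
  }
  post <- coh_of(interval)
  coh <- post$coh
  if (baseline_subtract) coh <- coh - coh_of("pre")$coh
  out <- list(freqs = post$freqs, coh = coh,
              pair = ep$channel_labels[pair],
              baseline_subtracted = baseline_subtract,
              n_segments = post$n_segments)
  class(out) <- "coherence_spectrum"
  out
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %s-%s, %d freqs, %d segments%s\n",
              x$pair[1], x$pair[2], length(x$freqs), x$n_segments,
              if (x$baseline_subtracted) ", baseline-subtracted" else ""))
  invisible(x)
}

#' Frequency of the coherence peak inside a band
#'
#' @param cs a `coherence_spectrum`.
#' @param band Hz pair; ties resolve to the lowest frequency.
#' @return Peak frequency in Hz.
#' @export
peak_coherence_frequency <- function(cs, band) {
  stopifnot(inherits(cs, "coherence_spectrum"))
  sel <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  if (!length(sel)) stopf("band [%g, %g] Hz outside the frequency grid", band[1], band[2])
  cs$freqs[sel][which.max(cs$coh[sel])]
}
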