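## Conditioning of raw recordings: acquisition-style causal low-pass +
## downsampling, stimulus-locked epoching, and zero-phase FIR band-passing
## for the phase/power analyses.

#' Low-pass filter and downsample a recording
#'
#' Applies a causal Butterworth low-pass (default 3 poles at 50 Hz, the
#' acquisition-chain convention) to every channel, then resamples to
#' `target_fs` with an anti-aliased polyphase FIR.  Event onsets are
#' re-indexed to the new rate.
#'
#' @param rec an `lfp_recording`.
#' @param cutoff low-pass corner frequency in Hz (-3 dB point).
#' @param order Butterworth order (poles).
#' @param target_fs output sampling rate in Hz.
#' @return A new `lfp_recording` at `target_fs`.
#' @export
lowpass_downsample <- function(rec, cutoff = 50, order = 3, target_fs = 200) {
  validate_recording(rec)
  fs <- rec$fs
  if (cutoff >= fs / 2) stopf("cutoff %g Hz is not below Nyquist %g Hz", cutoff, fs / 2)
  if (cutoff >= target_fs / 2)
    stopf("cutoff %g Hz would alias at the target rate %g Hz", cutoff, target_fs)
  bw <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filt <- t(apply(rec$data, 1, function(x) as.numeric(signal::filter(bw, x))))
  g <- ratio_reduce(target_fs, fs)
  ds <- t(apply(filt, 1, function(x) resample_poly(x, g[1], g[2])))
  n_new <- ncol(ds)
  ev <- rec$events
  ev$onset <- pmin(n_new, floor((ev$onset - 1) * target_fs / fs) + 1L)
  out <- list(data = ds, fs = target_fs, channel_labels = rec$channel_labels,
              events = ev,
              sweep_samples = if (is.null(rec$sweep_samples)) NULL
                              else round(rec$sweep_samples * target_fs / fs),
              seed = rec$seed, config = rec$config)
  rownames(out$data) <- rec$channel_labels
  class(out) <- "lfp_recording"
  validate_recording(out)
  out
}

ratio_reduce <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

## Rational-rate polyphase resampling by p/q: zero-stuff by p, anti-alias
## with a zero-phase windowed FIR (gain p, cutoff at the narrower Nyquist),
## decimate by q.  Edges use reflection padding.
resample_poly <- function(x, p, q) {
  n <- length(x)
  if (p == q) return(x)
  xu <- numeric(n * p)
  xu[seq(1, n * p, by = p)] <- x
  ord <- 2L * as.integer(10 * max(p, q))
  b <- signal::fir1(ord, 0.9 * min(1 / p, 1 / q))
  b <- b / sum(b) * p                     # exact unit DC gain before decimation
  h <- ord %/% 2L
  m <- length(xu)
  pad_l <- xu[pmin(m, (h + 1):2)]
  pad_r <- xu[pmax(1, (m - 1):(m - h))]
  y <- stats::filter(c(pad_l, xu, pad_r), b, method = "convolution", sides = 2)
  y <- as.numeric(y[(h + 1):(h + m)])
  y[seq(1, m, by = q)]
}

#' Cut a recording into stimulus-locked epochs
#'
#' One trial per event, each spanning `window` seconds around the event
#' onset.  Samples are copied verbatim (no resampling), so concatenating
#' adjacent epochs reproduces the source signal exactly.
#'
#' @param rec an `lfp_recording`.
#' @param window numeric pair, epoch limits in seconds relative to onset
#'   (default `c(-10, 10)`).
#' @param baseline numeric pair inside `window` and before 0, used downstream
#'   as the pre-stimulus reference (default `c(-10, 0)`).
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `fs`, `t0` (seconds of first sample), `labels` (class per
#'   trial), `channel_labels`, `baseline_window`, `response_window`.
#' @export
epoch <- function(rec, window = c(-10, 10), baseline = c(-10, 0)) {
  validate_recording(rec)
  if (length(window) != 2 || window[1] >= window[2])
    stopf("window must be an increasing pair of seconds")
  if (baseline[1] < window[1] || baseline[2] > window[2] || baseline[2] > 0)
    stopf("baseline must lie within the window and end at or before onset")
  fs <- rec$fs
  n_samp <- round((window[2] - window[1]) * fs)
  offset <- round(window[1] * fs)
  n_total <- ncol(rec$data)
  starts <- rec$events$onset + offset
  bad <- which(starts < 1 | (starts + n_samp - 1) > n_total)
  if (length(bad))
    stopf("events out of bounds for window [%g, %g] s: %s",
          window[1], window[2], paste(bad, collapse = ", "))
  n_trials <- nrow(rec$events)
  n_chan <- nrow(rec$data)
  data <- array(0, dim = c(n_trials, n_chan, n_samp))
  for (i in seq_len(n_trials))
    data[i, , ] <- rec$data[, starts[i] + seq_len(n_samp) - 1L, drop = FALSE]
  ep <- list(data = data, fs = fs, t0 = window[1],
             labels = rec$events$class, channel_labels = rec$channel_labels,
             baseline_window = baseline,
             response_window = c(max(0, window[1]), window[2]))
  class(ep) <- "epoch_set"
  validate_epochs(ep)
  ep
}

validate_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  if (length(d) != 3) stopf("epoch data must be trials x channels x samples")
  if (length(ep$labels) != d[1]) stopf("labels length must equal trial count")
  if (anyNA(ep$data)) stopf("epochs contain NA")
  invisible(ep)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trial(s) x %d channel(s) x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$fs, x$t0))
  if (d[1] > 0) {
    tb <- table(x$labels)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an epoch set by trial
#'
#' @param ep an `epoch_set`.
#' @param trials integer or logical trial selector.
#' @return The `epoch_set` restricted to the selected trials.
#' @export
epoch_subset <- function(ep, trials) {
  validate_epochs(ep)
  out <- ep
  out$data <- ep$data[trials, , , drop = FALSE]
  out$labels <- ep$labels[trials]
  attr(out, "band") <- attr(ep, "band")
  out
}

## time axis of an epoch_set, seconds relative to stimulus onset
epoch_times <- function(ep) ep$t0 + (seq_len(dim(ep$data)[3]) - 1) / ep$fs

## sample index range for a seconds interval [a, b)
interval_index <- function(ep, interval) {
  tt <- epoch_times(ep)
  idx <- which(tt >= interval[1] & tt < interval[2])
  if (!length(idx)) stopf("interval [%g, %g) s outside the epoch", interval[1], interval[2])
  idx
}

## Zero-phase band-pass of a single vector: even-order (odd-length,
## symmetric) Hamming FIR applied by centered convolution on a
## reflection-padded signal — linear phase plus exact delay compensation,
## i.e. zero net group delay.
fir_bandpass_vec <- function(x, fs, lo, hi, order = NULL) {
  if (lo <= 0 || hi <= lo || hi >= fs / 2)
    stopf("need 0 < lo < hi < fs/2")
  n <- length(x)
  if (is.null(order)) order <- round(3.3 * fs / (hi - lo))
  order <- min(as.integer(order), 2L * ((n - 1L) %/% 2L) - 2L)
  order <- max(10L, order)
  if (order %% 2 == 1L) order <- order + 1L
  h <- order %/% 2L
  if (h >= n)
    stopf("band [%g, %g] Hz too narrow for a %d-sample signal at fs = %g",
          lo, hi, n, fs)
  b <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  xp <- c(2 * x[1] - x[(h + 1):2], x, 2 * x[n] - x[(n - 1):(n - h)])
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y[(h + 1):(h + n)])
}

#' Zero-phase band-pass filtering of an epoch set
#'
#' Filters every trial and channel with a linear-phase Hamming-window FIR
#' applied forward and backward (`filtfilt`), giving zero group delay.  The
#' default order targets a transition width about equal to the band width;
#' stopband attenuation exceeds 40 dB an octave outside the band.
#'
#' @param ep an `epoch_set`.
#' @param lo,hi band edges in Hz (half-open convention `[lo, hi)` when used
#'   for the consecutive 1 Hz bins).
#' @param order optional FIR order (even); default from the band width.
#' @return A filtered `epoch_set` with a `band` attribute.
#' @export
bandpass_zero_phase <- function(ep, lo, hi, order = NULL) {
  validate_epochs(ep)
  d <- dim(ep$data)
  out <- ep
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out$data[i, j, ] <- fir_bandpass_vec(ep$data[i, j, ], ep$fs, lo, hi, order)
  attr(out, "band") <- c(lo, hi)
  out
}
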