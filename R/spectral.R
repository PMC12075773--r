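## Welch spectra, complex Morlet scaleograms, baseline normalization and
## peak-frequency trajectories.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

## Welch auto/cross spectral estimation on a list of equal-length signals.
## Returns one-sided spectra; `y` NULL gives the PSD of `x`.  Segments are
## mean-detrended and Hann-tapered; density scaling (1/(fs*U)) so that the
## integrated PSD approximates the signal variance (Parseval).
welch_xspec <- function(x, y = NULL, fs, nwin = 500, nover = 350) {
  n <- length(x)
  if (nover >= nwin) stopf("overlap must be smaller than the window")
  if (n < nwin) stopf("interval (%d samples) shorter than one %d-sample window", n, nwin)
  step <- nwin - nover
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- hann_window(nwin)
  U <- sum(w^2)
  nf <- nwin %/% 2 + 1L
  acc <- complex(nf)
  for (s in starts) {
    xs <- x[s + seq_len(nwin) - 1L]; xs <- w * (xs - mean(xs))
    X <- stats::fft(xs)[seq_len(nf)]
    if (is.null(y)) {
      acc <- acc + X * Conj(X)
    } else {
      ys <- y[s + seq_len(nwin) - 1L]; ys <- w * (ys - mean(ys))
      Y <- stats::fft(ys)[seq_len(nf)]
      acc <- acc + Conj(X) * Y
    }
  }
  p <- acc / (length(starts) * fs * U)
  scale2 <- rep(2, nf); scale2[1] <- 1
  if (nwin %% 2 == 0) scale2[nf] <- 1
  list(freqs = (seq_len(nf) - 1) * fs / nwin, spec = p * scale2,
       n_segments = length(starts))
}

resolve_interval <- function(ep, interval) {
  if (is.character(interval))
    switch(match.arg(interval, c("pre", "post")),
           pre = ep$baseline_window, post = ep$response_window)
  else interval
}

#' Welch power spectrum of an epoch set
#'
#' One-sided Welch PSD (Hann taper, default 500-sample windows with
#' 350-sample overlap) computed per trial over `interval` and averaged across
#' trials for one channel.
#'
#' @param ep an `epoch_set`.
#' @param channel channel index or label.
#' @param window,overlap Welch segment length and overlap in samples.
#' @param interval `"pre"`, `"post"`, or a seconds pair relative to onset.
#' @param trials optional trial subset (indices or logical).
#' @return An `lfp_spectrum`: list with `freqs`, `power`, `n_trials_averaged`,
#'   `baseline_subtracted`, `channel`.
#' @export
welch_spectrum <- function(ep, channel = 1, window = 500, overlap = 350,
                           interval = "post", trials = NULL) {
  validate_epochs(ep)
  if (is.character(channel)) channel <- match(channel, ep$channel_labels)
  idx <- interval_index(ep, resolve_interval(ep, interval))
  tr <- seq_len(dim(ep$data)[1])
  if (!is.null(trials)) tr <- tr[trials]
  if (!length(tr)) stopf("no trials selected")
  acc <- NULL
  for (i in tr) {
    ps <- welch_xspec(ep$data[i, channel, idx], NULL, ep$fs, window, overlap)
    acc <- if (is.null(acc)) ps else { ps$spec <- ps$spec + acc$spec; ps }
  }
  out <- list(freqs = acc$freqs, power = Re(acc$spec) / length(tr),
              n_trials_averaged = length(tr), baseline_subtracted = FALSE,
              channel = ep$channel_labels[channel])
  class(out) <- "lfp_spectrum"
  out
}

#' Subtract a baseline spectrum from a post-stimulus spectrum
#'
#' @param post_spec,pre_spec `lfp_spectrum` objects on identical frequency
#'   grids (typically the 10 s after and the 10 s before the stimulus).
#' @return `lfp_spectrum` with `power = post - pre` and
#'   `baseline_subtracted = TRUE` (values may be negative).
#' @export
baseline_subtract <- function(post_spec, pre_spec) {
  stopifnot(inherits(post_spec, "lfp_spectrum"), inherits(pre_spec, "lfp_spectrum"))
  if (length(post_spec$freqs) != length(pre_spec$freqs) ||
      any(abs(post_spec$freqs - pre_spec$freqs) > 1e-9))
    stopf("frequency grids differ")
  out <- post_spec
  out$power <- post_spec$power - pre_spec$power
  out$baseline_subtracted <- TRUE
  out
}

#' @export
print.lfp_spectrum <- function(x, ...) {
  cat(sprintf("<lfp_spectrum> channel %s, %d frequencies (%g-%g Hz), %d trial(s)%s\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_trials_averaged,
              if (x$baseline_subtracted) ", baseline-subtracted" else ""))
  invisible(x)
}

## Fourier transform of the complex Morlet mother wavelet
## psi(t) = c_sigma * pi^(-1/4) * exp(-t^2/2) * (exp(i*sigma*t) - kappa),
## kappa = exp(-sigma^2/2) being the zero-mean (admissibility) correction.
morlet_psihat <- function(omega, sigma = 5) {
  kappa <- exp(-sigma^2 / 2)
  c_sig <- (1 + exp(-sigma^2) - 2 * exp(-0.75 * sigma^2))^(-1 / 2)
  c_sig * pi^(-1 / 4) * sqrt(2 * pi) *
    (exp(-0.5 * (sigma - omega)^2) - kappa * exp(-0.5 * omega^2))
}

## time-domain mother wavelet (for admissibility checks)
morlet_psi <- function(t, sigma = 5) {
  kappa <- exp(-sigma^2 / 2)
  c_sig <- (1 + exp(-sigma^2) - 2 * exp(-0.75 * sigma^2))^(-1 / 2)
  c_sig * pi^(-1 / 4) * exp(-t^2 / 2) * (exp(1i * sigma * t) - kappa)
}

#' Morlet scaleogram of a single trial
#'
#' Continuous wavelet transform with the complex Morlet wavelet
#' (default `sigma = 5`), evaluated in the frequency domain, returning the
#' scaleogram `|W(t, s)|^2`.  Scales are mapped to target frequencies via the
#' wavelet's center frequency, `s = sigma / (2 pi f)`; the coarser
#' period-scale relation `T ~ s / sigma` holds up to that constant.
#'
#' @param x numeric signal (one trial, one channel).
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid in Hz (inside (0, fs/2)).
#' @param sigma Morlet central-frequency parameter.
#' @param t0 time of the first sample in seconds (for the time axis).
#' @return A `tf_map`: list with `freqs`, `times`, `values`
#'   (frequencies x times), `units` = `"power"`.
#' @export
cwt_scaleogram <- function(x, fs, freqs, sigma = 5, t0 = 0) {
  n <- length(x)
  if (any(freqs <= 0 | freqs >= fs / 2)) stopf("freqs must lie in (0, fs/2)")
  k <- seq_len(n) - 1
  fgrid <- ifelse(k <= n / 2, k, k - n) * fs / n
  omega <- 2 * pi * fgrid
  X <- stats::fft(x)
  vals <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- sigma / (2 * pi * freqs[i])
    W <- stats::fft(X * morlet_psihat(s * omega, sigma), inverse = TRUE) / n
    vals[i, ] <- Mod(W)^2
  }
  out <- list(freqs = freqs, times = t0 + (seq_len(n) - 1) / fs,
              values = vals, units = "power")
  class(out) <- "tf_map"
  out
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freqs (%g-%g Hz) x %d times (%g-%g s), units %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times), x$units))
  invisible(x)
}

#' Z-score a time-frequency map against a baseline interval
#'
#' Per frequency row, subtracts the mean and divides by the SD of the values
#' inside the baseline interval, expressing the map in baseline SD units.
#'
#' @param tf a `tf_map`.
#' @param baseline seconds pair `[a, b)` inside `tf$times`.
#' @return A `tf_map` with `units = "zscore"`.
#' @export
zscore_map <- function(tf, baseline) {
  stopifnot(inherits(tf, "tf_map"))
  idx <- which(tf$times >= baseline[1] & tf$times < baseline[2])
  if (!length(idx)) stopf("baseline interval outside map times")
  m <- rowMeans(tf$values[, idx, drop = FALSE])
  s <- apply(tf$values[, idx, drop = FALSE], 1, stats::sd)
  if (any(s == 0))
    stopf("zero baseline variance at frequency rows: %s",
          paste(which(s == 0), collapse = ", "))
  out <- tf
  out$values <- (tf$values - m) / s
  out$units <- "zscore"
  out
}

#' Peak-frequency trajectory across experiments
#'
#' For each experiment's (z-scored) time-frequency map, finds at every time
#' point the frequency of maximum value within `band`; the across-experiment
#' mean and standard error are reported only at times where more than half of
#' the experiments exceed `z_thresh` somewhere within the band, and are
#' masked (`NA`) elsewhere.
#'
#' @param maps list of `tf_map`s on a common grid (one per experiment).
#' @param z_thresh threshold on the map value (default 5, z-score units).
#' @param band Hz pair searched for the maximum (default `c(5, 20)`).
#' @return data.frame with `time`, `mean_freq`, `se_freq`, `n_above`,
#'   `valid`.
#' @export
peak_frequency_trace <- function(maps, z_thresh = 5, band = c(5, 20)) {
  if (!length(maps)) stopf("need at least one map")
  f <- maps[[1]]$freqs; tt <- maps[[1]]$times
  rows <- which(f >= band[1] & f <= band[2])
  if (!length(rows)) stopf("band outside the frequency grid")
  peak <- vapply(maps, function(m) {
    sub <- m$values[rows, , drop = FALSE]
    f[rows][max.col(t(sub), ties.method = "first")]
  }, numeric(length(tt)))
  above <- vapply(maps, function(m)
    apply(m$values[rows, , drop = FALSE], 2, max) > z_thresh,
    logical(length(tt)))
  peak <- matrix(peak, nrow = length(tt))
  above <- matrix(above, nrow = length(tt))
  n_above <- rowSums(above)
  valid <- n_above > length(maps) / 2
  mf <- rowMeans(peak); sf <- apply(peak, 1, stats::sd) / sqrt(length(maps))
  mf[!valid] <- NA_real_; sf[!valid] <- NA_real_
  data.frame(time = tt, mean_freq = mf, se_freq = sf,
             n_above = n_above, valid = valid)
}
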