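## Hilbert analytic signals and phase-lag indices (PLI / wPLI) with
## sliding-window time courses z-scored to the pre-stimulus baseline.

## FFT-based analytic signal (one-sided spectrum doubling)
analytic_signal_vec <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) stopf("analytic signal of a constant is undefined")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Analytic signal of a band-passed epoch set
#'
#' Computes, per trial and channel, the Hilbert analytic signal
#' `xi(t) = x(t) + i x_h(t)`; its modulus is the instantaneous amplitude
#' envelope and its argument the instantaneous phase.  The input must
#' already be narrow-band (see [bandpass_zero_phase()]) for the phase to be
#' interpretable.
#'
#' @param ep an `epoch_set`, band-pass filtered.
#' @return An `analytic_set`: list with complex array `xi` (trials x channels
#'   x samples), plus `amplitude` and `phase` accessors via `$`, `fs`, `t0`,
#'   `labels`, `channel_labels`, `band` (from the filtering step, if any).
#' @export
analytic_signal <- function(ep) {
  validate_epochs(ep)
  d <- dim(ep$data)
  xi <- array(complex(1), dim = d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      xi[i, j, ] <- analytic_signal_vec(ep$data[i, j, ])
  out <- list(xi = xi, fs = ep$fs, t0 = ep$t0, labels = ep$labels,
              channel_labels = ep$channel_labels,
              baseline_window = ep$baseline_window,
              band = attr(ep, "band"))
  class(out) <- "analytic_set"
  out
}

#' @export
print.analytic_set <- function(x, ...) {
  d <- dim(x$xi)
  cat(sprintf("<analytic_set> %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

## Core estimators on the imaginary part of the cross-term
## S_xy = xi_x * Conj(xi_y), pooled over all supplied elements.
## Perfectly zero-lag data (all Im S = 0) give 0 by convention, flagged.
wpli_value <- function(im_s) {
  den <- sum(abs(im_s))
  if (den == 0) return(structure(0, degenerate = TRUE))
  abs(sum(im_s)) / den
}

pli_value <- function(im_s) {
  n <- length(im_s)
  if (n == 0) stopf("empty window")
  abs(sum(sign(im_s))) / n
}

#' PLI and wPLI over a pooled window of trials
#'
#' Evaluates the phase lag index
#' `PLI = |sum sgn(Im S_xy)| / n` and the weighted phase lag index
#' `wPLI = |sum |Im S_xy| sgn(Im S_xy)| / sum |Im S_xy|`
#' from the complex cross-terms `S_xy = xi_x conj(xi_y)`, pooling trials and
#' within-window samples.  Both lie in \[0, 1\]: 1 for a constant nonzero
#' phase difference across trials, near 0 for random phase differences.
#' Purely zero-lag (or anti-phase) data make every imaginary part vanish;
#' the estimators then return 0 with attribute `degenerate = TRUE`.
#'
#' @param xi_x,xi_y complex matrices (trials x samples) of analytic signals,
#'   or numeric/complex vectors.
#' @param window optional sample (column) indices to pool; default all.
#' @return wPLI (or PLI) value in \[0, 1\].
#' @export
wpli_window <- function(xi_x, xi_y, window = NULL) {
  s <- xi_x * Conj(xi_y)
  if (!is.null(window)) s <- if (is.matrix(s)) s[, window, drop = FALSE] else s[window]
  wpli_value(Im(s))
}

#' @rdname wpli_window
#' @export
pli_window <- function(xi_x, xi_y, window = NULL) {
  s <- xi_x * Conj(xi_y)
  if (!is.null(window)) s <- if (is.matrix(s)) s[, window, drop = FALSE] else s[window]
  pli_value(Im(s))
}

#' Sliding-window wPLI time course between two channels
#'
#' Filters the pair into consecutive 1 Hz-wide bins spanning `band`
#' (half-open bins, default 6--10 Hz -> bins \[6,7) ... \[9,10)), takes
#' Hilbert analytic signals, forms the cross-terms, and evaluates wPLI (or
#' PLI) in sliding windows (default 500 ms length, 2 ms step — steps shorter
#' than one sample at the working rate are rounded up to one sample).  Within
#' a window the sum pools all trials and samples; bin traces are averaged
#' into one band trace and expressed as z-scores relative to the pre-stimulus
#' baseline windows.
#'
#' @param ep a broadband `epoch_set`.
#' @param pair two channel indices or labels.
#' @param band Hz pair covered by the 1 Hz bins.
#' @param bin_width width of each filter bin in Hz.
#' @param window_s,step_s sliding window length and step in seconds.
#' @param baseline seconds pair of the pre-stimulus reference (default the
#'   1 s before onset).
#' @param measure `"wpli"` or `"pli"`.
#' @return A `conn_timecourse`: list with `times` (window centers, s),
#'   `raw`, `z`, `pair`, `band`, `measure`, `n_trials`, `window_s`, `step_s`.
#' @export
wpli_timecourse <- function(ep, pair = c(1, 2), band = c(6, 10), bin_width = 1,
                            window_s = 0.5, step_s = 0.002,
                            baseline = c(-1, 0), measure = c("wpli", "pli")) {
  validate_epochs(ep)
  measure <- match.arg(measure)
  if (is.character(pair)) pair <- match(pair, ep$channel_labels)
  fs <- ep$fs
  d <- dim(ep$data)
  if (d[1] < 2) stopf("need >= 2 trials")
  wlen <- max(2L, round(window_s * fs))
  step <- max(1L, round(step_s * fs))
  n <- d[3]
  if (wlen > n) stopf("window longer than the epoch")
  starts <- seq(1L, n - wlen + 1L, by = step)
  centers <- ep$t0 + (starts + (wlen - 1) / 2 - 1) / fs
  bins_lo <- seq(band[1], band[2] - bin_width, by = bin_width)
  vals <- matrix(0, length(bins_lo), length(starts))
  for (bi in seq_along(bins_lo)) {
    lo <- bins_lo[bi]; hi <- lo + bin_width
    im_sum <- numeric(n); abs_sum <- numeric(n); sgn_sum <- numeric(n)
    for (i in seq_len(d[1])) {
      x <- fir_bandpass_vec(ep$data[i, pair[1], ], fs, lo, hi)
      y <- fir_bandpass_vec(ep$data[i, pair[2], ], fs, lo, hi)
      im_s <- Im(analytic_signal_vec(x) * Conj(analytic_signal_vec(y)))
      im_sum <- im_sum + im_s
      abs_sum <- abs_sum + abs(im_s)
      sgn_sum <- sgn_sum + sign(im_s)
    }
    c_im <- c(0, cumsum(im_sum)); c_abs <- c(0, cumsum(abs_sum))
    c_sgn <- c(0, cumsum(sgn_sum))
    num <- if (measure == "wpli") abs(c_im[starts + wlen] - c_im[starts])
           else abs(c_sgn[starts + wlen] - c_sgn[starts])
    den <- if (measure == "wpli") (c_abs[starts + wlen] - c_abs[starts])
           else rep(wlen * d[1], length(starts))
    v <- ifelse(den == 0, 0, num / den)
    vals[bi, ] <- v
  }
  raw <- colMeans(vals)
  bl <- which(centers >= baseline[1] & centers < baseline[2])
  if (!length(bl)) stopf("baseline interval contains no window centers")
  mu <- mean(raw[bl]); sdv <- stats::sd(raw[bl])
  if (sdv == 0) stopf("zero baseline variance in the %s trace", measure)
  out <- list(times = centers, raw = raw, z = (raw - mu) / sdv,
              pair = ep$channel_labels[pair], band = band, measure = measure,
              n_trials = d[1], window_s = wlen / fs, step_s = step / fs)
  class(out) <- "conn_timecourse"
  out
}

#' @export
print.conn_timecourse <- function(x, ...) {
  cat(sprintf("<conn_timecourse> %s %s-%s, band %g-%g Hz, %d windows (%g s / %g s), %d trials\n",
              x$measure, x$pair[1], x$pair[2], x$band[1], x$band[2],
              length(x$times), x$window_s, x$step_s, x$n_trials))
  invisible(x)
}

#' Mean of a connectivity time course over a window
#'
#' @param tc a `conn_timecourse`.
#' @param window seconds pair (default the 1--5 s post-stimulus range used
#'   for summary distributions).
#' @param what `"raw"` or `"z"`.
#' @return Scalar mean over window centers inside `window`.
#' @export
timecourse_mean <- function(tc, window = c(1, 5), what = c("raw", "z")) {
  stopifnot(inherits(tc, "conn_timecourse"))
  what <- match.arg(what)
  idx <- which(tc$times >= window[1] & tc$times < window[2])
  if (!length(idx)) stopf("window [%g, %g] s outside the time course", window[1], window[2])
  mean(tc[[what]][idx])
}
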