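## Weighted symbolic mutual information: ordinal symbolization of LFP
## signals, the identical/opposite-symbol weight matrix, and sliding-window
## wSMI time courses.

## all permutations of 1:k (rows), lexicographic
permutations_k <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_k(k - 1)
  out <- NULL
  for (v in seq_len(k)) {
    rest <- setdiff(seq_len(k), v)
    out <- rbind(out, cbind(v, matrix(rest[sub], nrow(sub), k - 1)))
  }
  unname(out)
}

## Lehmer-style code (1-based) of the value pattern in each row of m
## (columns = the k temporally ordered samples).  Ties resolve by temporal
## order: a later equal sample counts as larger.
pattern_codes <- function(m) {
  k <- ncol(m)
  f <- factorial((k - 1):0)
  code <- rep(0, nrow(m))
  for (j in seq_len(k - 1)) {
    cj <- rep(0, nrow(m))
    for (l in (j + 1):k) cj <- cj + (m[, l] < m[, j])
    code <- code + cj * f[j]
  }
  as.integer(code + 1L)
}

## code of each symbol's "opposite" (the pattern of the negated signal)
opposite_codes <- function(k) {
  p <- permutations_k(k)
  codes <- pattern_codes(p)
  opp <- pattern_codes(-p)
  out <- integer(factorial(k))
  out[codes] <- opp
  out
}

#' Ordinal symbolization of a signal
#'
#' Encodes the rank ordering of `k` samples spaced `tau` samples apart into
#' one of `k!` discrete symbols, sliding one sample at a time.  Ties are
#' broken by temporal order (earlier sample ranks lower), making the
#' transform deterministic on quantized data.  The symbol sequence is
#' invariant under any strictly increasing transform of the signal.
#'
#' @param x numeric signal.
#' @param k samples per symbol (default 3, giving 6 symbols).
#' @param tau sample spacing between the `k` samples (default 32, the 1 kHz
#'   millisecond convention; see [wsmi_tau_samples()] for other rates).
#' @return Integer vector of codes in `1..k!`, length
#'   `length(x) - (k-1)*tau`.
#' @export
symbolize <- function(x, k = 3, tau = 32) {
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (!is_count(tau)) stopf("tau must be a positive integer (samples)")
  n_sym <- length(x) - (k - 1) * tau
  if (n_sym < 1)
    stopf("signal too short: need more than (k-1)*tau = %d samples", (k - 1) * tau)
  m <- vapply(seq_len(k), function(j) x[(j - 1) * tau + seq_len(n_sym)],
              numeric(n_sym))
  pattern_codes(matrix(m, nrow = n_sym))
}

#' Convert the millisecond tau convention to samples
#'
#' The symbol spacing is defined in milliseconds at the original 1 kHz
#' acquisition convention (`f = 1000 / (tau * k)` Hz gives the frequency the
#' symbolization is most sensitive to; tau = 32, k = 3 targets ~6--10 Hz).
#' At a working rate `fs` the spacing becomes `round(tau_ms * fs / 1000)`
#' samples, floored at 1.
#'
#' @param tau_ms spacing in milliseconds.
#' @param fs sampling rate in Hz.
#' @return Integer number of samples.
#' @export
wsmi_tau_samples <- function(tau_ms = 32, fs = 1000) {
  max(1L, as.integer(round(tau_ms * fs / 1000)))
}

#' Weight matrix for weighted symbolic mutual information
#'
#' Binary `k! x k!` matrix that zeroes symbol pairs that could arise from a
#' single common source: identical symbols (diagonal) and opposite symbols
#' (the two sides of one dipole); all other pairs weigh 1.  Symmetric.
#'
#' @param k samples per symbol.
#' @return `k! x k!` 0/1 matrix.
#' @export
build_weights <- function(k = 3) {
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  nk <- factorial(k)
  w <- matrix(1, nk, nk)
  diag(w) <- 0
  opp <- opposite_codes(k)
  w[cbind(seq_len(nk), opp)] <- 0
  w
}

## wSMI from a joint symbol count matrix (k! x k!)
wsmi_from_counts <- function(counts, w, k) {
  n <- sum(counts)
  if (n == 0) stopf("empty joint distribution")
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  nz <- which(p > 0 & w > 0, arr.ind = TRUE)
  if (!nrow(nz)) return(0)
  pj <- p[nz]
  sum(pj * log(pj / (px[nz[, 1]] * py[nz[, 2]]))) / log(factorial(k))
}

#' Weighted symbolic mutual information between two symbol sequences
#'
#' `wSMI = (1/log k!) * sum w(x,y) p(x,y) log[p(x,y) / (p(x) p(y))]` over the
#' joint distribution of co-occurring symbols, with identical and opposite
#' symbol pairs weighted out ([build_weights()]).  Natural logs are used in
#' both the MI term and the `log k!` normalization (the base cancels).  A
#' signal paired with itself, or with its negation, gives exactly 0.
#'
#' @param sx,sy aligned integer symbol sequences from [symbolize()] (pooled
#'   over windows/trials).
#' @param k samples per symbol used in the symbolization.
#' @param weighted set `FALSE` for the unweighted symbolic MI.
#' @return Dimensionless value (>= 0 up to the normalization).
#' @export
wsmi_value <- function(sx, sy, k = 3, weighted = TRUE) {
  if (length(sx) != length(sy)) stopf("symbol sequences must be aligned")
  if (!length(sx)) stopf("empty symbol sequences")
  nk <- factorial(k)
  counts <- matrix(tabulate((sx - 1L) * nk + sy, nbins = nk * nk), nk, nk,
                   byrow = TRUE)
  w <- if (weighted) build_weights(k) else matrix(1, nk, nk)
  wsmi_from_counts(counts, w, k)
}

#' Sliding-window wSMI time course between two channels
#'
#' Symbolizes both channels of the pair trial by trial, then evaluates wSMI
#' in sliding windows (default 500 ms length, 2 ms step, rounded to whole
#' samples), pooling the joint symbol distribution across trials and
#' within-window symbol positions.  A symbol belongs to a window when all
#' `k` of its samples fall inside it.
#'
#' @param ep an `epoch_set` (broadband; the tau spacing sets the frequency
#'   sensitivity, no band-pass needed).
#' @param pair two channel indices or labels.
#' @param k samples per symbol.
#' @param tau_ms symbol spacing in milliseconds ([wsmi_tau_samples()]).
#' @param window_s,step_s sliding window length and step in seconds.
#' @param baseline seconds pair for the z-scored trace.
#' @return A `conn_timecourse` with `measure = "wsmi"`.
#' @export
wsmi_timecourse <- function(ep, pair = c(1, 2), k = 3, tau_ms = 32,
                            window_s = 0.5, step_s = 0.002,
                            baseline = c(-1, 0)) {
  validate_epochs(ep)
  if (is.character(pair)) pair <- match(pair, ep$channel_labels)
  fs <- ep$fs
  d <- dim(ep$data)
  tau <- wsmi_tau_samples(tau_ms, fs)
  span <- (k - 1L) * tau
  wlen <- max(2L, round(window_s * fs))
  if (wlen <= span)
    stopf("window (%d samples) must exceed the symbol span (k-1)*tau = %d", wlen, span)
  step <- max(1L, round(step_s * fs))
  n <- d[3]
  nk <- factorial(k)
  w <- build_weights(k)
  ## joint symbol code per trial and symbol start position
  n_sym <- n - span
  joint <- matrix(0L, d[1], n_sym)
  for (i in seq_len(d[1])) {
    sx <- symbolize(ep$data[i, pair[1], ], k, tau)
    sy <- symbolize(ep$data[i, pair[2], ], k, tau)
    joint[i, ] <- (sx - 1L) * nk + sy
  }
  starts <- seq(1L, n - wlen + 1L, by = step)
  centers <- ep$t0 + (starts + (wlen - 1) / 2 - 1) / fs
  per_window <- wlen - span
  raw <- vapply(starts, function(s) {
    jw <- joint[, s + seq_len(per_window) - 1L]
    counts <- matrix(tabulate(jw, nbins = nk * nk), nk, nk, byrow = TRUE)
    wsmi_from_counts(counts, w, k)
  }, numeric(1))
  bl <- which(centers >= baseline[1] & centers < baseline[2])
  z <- if (length(bl) && stats::sd(raw[bl]) > 0)
    (raw - mean(raw[bl])) / stats::sd(raw[bl]) else rep(NA_real_, length(raw))
  f_sens <- 1000 / (tau_ms * k)   # designed frequency sensitivity, Hz
  out <- list(times = centers, raw = raw, z = z,
              pair = ep$channel_labels[pair], band = c(f_sens, f_sens),
              measure = "wsmi", n_trials = d[1],
              window_s = wlen / fs, step_s = step / fs, k = k, tau = tau)
  class(out) <- "conn_timecourse"
  out
}
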