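## Shared fixtures: small, fast synthetic configurations.

## compact experiment: short sweeps, few trials, 500 Hz
small_config <- function(...) {
  defaults <- list(n_trials_per_class = 4,
                   classes = c("AA", "BS", "TW"),
                   control_class = "TW",
                   class_freq_offsets = c(AA = 0, BS = 1, TW = 0),
                   sweep_duration = 16, stim_onset = 5, stim_duration = 1,
                   fs = 500, evoked_duration = c(6, 8))
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

## matched pair of narrow-band "sender"/"receiver" trial sets for direct
## estimator checks; returns pooled symbol sequences and analytic matrices
coupled_trials <- function(n_trials = 20, n = 400, fs = 200, snr_noise = 0.5,
                           kind = c("nonlinear", "none"), tau = NULL) {
  kind <- match.arg(kind)
  if (is.null(tau)) tau <- wsmi_tau_samples(32, fs)
  hx <- hy <- matrix(0 + 0i, n_trials, n)
  sx <- sy <- NULL
  for (i in seq_len(n_trials)) {
    tv <- seq_len(n) / fs
    x <- cos(2 * pi * 8 * tv + stats::runif(1, 0, 2 * pi)) +
      snr_noise * stats::rnorm(n)
    y <- if (kind == "nonlinear")
      odd_transform(x, list(type = "tanh", gain = 3)) + snr_noise * stats::rnorm(n)
    else
      cos(2 * pi * 8 * tv + stats::runif(1, 0, 2 * pi)) + snr_noise * stats::rnorm(n)
    bx <- olfconn:::fir_bandpass_vec(x, fs, 6, 10)
    by <- olfconn:::fir_bandpass_vec(y, fs, 6, 10)
    hx[i, ] <- olfconn:::analytic_signal_vec(bx)
    hy[i, ] <- olfconn:::analytic_signal_vec(by)
    sx <- c(sx, symbolize(x, 3, tau))
    sy <- c(sy, symbolize(y, 3, tau))
  }
  list(sx = sx, sy = sy, hx = hx, hy = hy)
}

## analytic-signal trial matrices of an 8 Hz tone with chosen per-trial lags
tone_pair <- function(lags, fs = 200, dur = 2, f = 8) {
  tv <- seq_len(round(dur * fs)) / fs
  phi <- stats::runif(length(lags), 0, 2 * pi)
  xi_x <- t(vapply(phi, function(p) exp(1i * (2 * pi * f * tv + p)),
                   complex(length(tv))))
  xi_y <- xi_x * exp(-1i * matrix(lags, length(lags), length(tv)))
  list(x = xi_x, y = xi_y)
}
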