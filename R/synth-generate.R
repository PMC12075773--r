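## Synthetic LFP generation: baseline noise, evoked chirps, inter-region
## coupling and class-amplitude encoding.

#' Monotone odd nonlinearity
#'
#' Applies a sign-symmetric, strictly monotone transform to a signal and
#' rescales the result to the input's standard deviation.  Monotone odd
#' transforms preserve the rank ordering of samples (so ordinal-pattern
#' measures such as wSMI see the same temporal patterns) while redistributing
#' energy into harmonics.
#'
#' @param x numeric signal.
#' @param spec list: `type` is `"tanh"` (soft clipping, `gain` sets how hard)
#'   or `"power"` (signed power law, `exponent` in (0, 1]).
#' @return Transformed signal with `sd(x)` restored.
#' @export
odd_transform <- function(x, spec = list(type = "tanh", gain = 3)) {
  s <- stats::sd(x)
  if (s == 0) return(x)
  y <- switch(spec$type,
              tanh  = tanh((if (is.null(spec$gain)) 3 else spec$gain) * x / s),
              power = sign(x) * abs(x / s)^(if (is.null(spec$exponent)) 1 / 3
                                            else spec$exponent),
              stopf("unknown nonlinearity type '%s'", spec$type))
  y * s / stats::sd(y)
}

## 1/f-ish baseline: pink noise (FFT 1/sqrt(f) shaping) plus a low-pass AR(1)
## bump below `lf_cutoff` Hz; unit variance.
baseline_noise <- function(n, fs, spec = list(pink_weight = 1, lf_weight = 1.5,
                                              lf_cutoff = 3)) {
  ## pink component
  z <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))            # avoid DC blow-up
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency index
  z <- z / sqrt(f)
  pink <- Re(stats::fft(z, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink)
  ## AR(1) with cutoff lf_cutoff Hz at this fs
  phi <- exp(-2 * pi * spec$lf_cutoff / fs)
  ar <- stats::filter(stats::rnorm(n), phi, method = "recursive")
  ar <- as.numeric(ar) / stats::sd(ar)
  x <- spec$pink_weight * pink + spec$lf_weight * ar
  x / stats::sd(x)
}

## Amplitude-enveloped chirp: zero before `onset`, raised-cosine ramps, and an
## instantaneous frequency declining by chirp_rate Hz/s for chirp_time s.
## Returns list(signal, phase) over the full sweep; phase is NA outside the
## evoked support.
evoked_chirp <- function(n, fs, onset, dur, f_start, chirp_rate, chirp_time,
                         phi0 = 0, ramp_up = 0.5, ramp_down = 1) {
  sig <- numeric(n)
  i0 <- floor(onset * fs) + 1L
  i1 <- min(n, floor((onset + dur) * fs))
  if (i0 >= i1) return(list(signal = sig, phase = rep(NA_real_, n)))
  t_rel <- (seq.int(i0, i1) - i0) / fs
  f_inst <- pmax(0.1, f_start - chirp_rate * pmin(t_rel, chirp_time))
  phase <- phi0 + 2 * pi * cumsum(f_inst) / fs
  env <- rep(1, length(t_rel))
  ru <- pmin(ramp_up, dur / 4); rd <- pmin(ramp_down, dur / 4)
  up <- t_rel < ru
  env[up] <- 0.5 * (1 - cos(pi * t_rel[up] / ru))
  down <- t_rel > (max(t_rel) - rd)
  env[down] <- 0.5 * (1 - cos(pi * (max(t_rel) - t_rel[down]) / rd))
  sig[i0:i1] <- env * cos(phase)
  ph <- rep(NA_real_, n); ph[i0:i1] <- phase
  list(signal = sig, phase = ph)
}

#' Realize an inter-region coupling of an evoked waveform
#'
#' Given a sender's waveform, produces the component injected into a receiver
#' region under one of three coupling regimes:
#' * `"none"` — an independent realization with the same spectrum (Fourier
#'   phase-randomized surrogate of the sender);
#' * `"linear_lag"` — the sender waveform with a constant phase shift of
#'   `lag` radians (applied by rotating the analytic signal), preserving the
#'   spectral peak and a fixed cross-phase;
#' * `"nonlinear"` — a monotone odd transform of the sender waveform at zero
#'   lag ([odd_transform()]).  Rank-order temporal patterns survive (so
#'   ordinal-pattern coupling measures can detect it) while the zero lag makes
#'   the interaction invisible to lag-based phase metrics.
#'
#' Independent Gaussian noise of standard deviation `noise_sd` is added in all
#' cases.
#'
#' @param sender numeric waveform of the sending region.
#' @param kind coupling kind, see above.
#' @param lag radians (for `"linear_lag"`).
#' @param nonlinearity transform spec (for `"nonlinear"`), see
#'   [odd_transform()].
#' @param noise_sd SD of the independent additive receiver noise.
#' @param seed optional integer for reproducibility.
#' @return Numeric vector, the receiver component.
#' @export
realize_coupling <- function(sender, kind = c("none", "linear_lag", "nonlinear"),
                             lag = pi / 2,
                             nonlinearity = list(type = "tanh", gain = 3),
                             noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  run <- function() {
    y <- switch(kind,
      none = {
        z <- stats::fft(sender)
        n <- length(sender)
        nh <- (n - 1) %/% 2
        th <- stats::runif(nh, 0, 2 * pi)
        rot <- rep(1 + 0i, n)
        rot[2:(nh + 1)] <- exp(1i * th)
        rot[n:(n - nh + 1)] <- Conj(rot[2:(nh + 1)])
        Re(stats::fft(z * rot, inverse = TRUE)) / n
      },
      linear_lag = Re(analytic_signal_vec(sender) * exp(-1i * lag)),
      nonlinear = odd_transform(sender, nonlinearity))
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
    y
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Per-region class-amplitude gains
#'
#' Draws the multiplicative evoked-amplitude gains that write stimulus-class
#' information into each region:
#' * `"redundant"` — one shared class-dependent gain for every region, so all
#'   regions carry the same information (positive co-information);
#' * `"independent"` — each region uses its own (rotated) class-to-gain
#'   mapping;
#' * `"synergistic"` — the first two regions get an XOR-style pairing: the
#'   class determines only whether their gains agree or disagree, a random
#'   per-trial bit picks which configuration, so neither region alone is
#'   informative but the pair is (negative co-information).
#'
#' Called once per trial inside [generate_recording()]; the synergistic mode
#' consumes one random draw from the current RNG stream.
#'
#' @param mode encoding mode.
#' @param class_index integer index of the trial's class.
#' @param n_classes,n_regions counts.
#' @param separation half-range of the gain spread (0 = no class information).
#' @return Numeric vector of `n_regions` gains around 1.
#' @export
realize_class_encoding <- function(mode = c("independent", "redundant", "synergistic"),
                                   class_index, n_classes, n_regions,
                                   separation = 0.4) {
  mode <- match.arg(mode)
  if (!is_count(class_index) || class_index > n_classes)
    stopf("class_index out of range")
  base <- if (n_classes > 1)
    seq(1 - separation, 1 + separation, length.out = n_classes) else 1
  switch(mode,
    redundant = rep(base[class_index], n_regions),
    independent = vapply(seq_len(n_regions), function(r) {
      base[((class_index - 1 + (r - 1)) %% n_classes) + 1]
    }, numeric(1)),
    synergistic = {
      b <- stats::runif(1) < 0.5
      parity <- (class_index %% 2) == 0
      hi <- 1 + separation; lo <- 1 - separation
      g12 <- if (parity) { if (b) c(hi, hi) else c(lo, lo) }
             else        { if (b) c(hi, lo) else c(lo, hi) }
      c(g12, rep(1, max(0, n_regions - 2)))[seq_len(n_regions)]
    })
}

#' Generate a synthetic multi-region LFP recording
#'
#' Simulates the full stimulation protocol described by a [synth_config()]:
#' for every class and trial, one sweep of baseline noise in each region, plus
#' (for non-control classes) an odor-evoked narrow-band chirp starting at the
#' stimulus onset.  The first region acts as the sender; receiver regions get
#' their evoked component through [realize_coupling()] semantics, and
#' class-amplitude information is injected per [realize_class_encoding()].
#' Sweeps are generated from per-sweep seeds derived from `config$seed`, so
#' the result is bit-reproducible.
#'
#' @param config a [synth_config()].
#' @return An `lfp_recording`: list with `data` (regions x samples matrix of
#'   concatenated sweeps), `fs`, `channel_labels`, `events` (data.frame with
#'   `onset` sample and `class` per sweep), `sweep_samples`, and `seed`.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  fs <- cfg$fs
  ns <- round(cfg$sweep_duration * fs)
  n_regions <- length(cfg$regions)
  n_classes <- length(cfg$classes)
  n_sweeps <- n_classes * cfg$n_trials_per_class
  seeds <- derive_seeds(cfg$seed, n_sweeps)

  data <- matrix(0, n_regions, ns * n_sweeps)
  onsets <- integer(n_sweeps)
  classes_out <- character(n_sweeps)
  sweep <- 0L
  for (trial in seq_len(cfg$n_trials_per_class)) {
    for (ci in seq_along(cfg$classes)) {
      sweep <- sweep + 1L
      cls <- cfg$classes[ci]
      block <- with_seed(seeds[sweep], {
        x <- vapply(seq_len(n_regions),
                    function(r) baseline_noise(ns, fs, cfg$baseline_spectrum),
                    numeric(ns))
        x <- t(x)                       # regions x samples
        if (cls != cfg$control_class && cfg$snr > 0) {
          dur <- stats::runif(1, cfg$evoked_duration[1], cfg$evoked_duration[2])
          dur <- min(dur, cfg$sweep_duration - cfg$stim_onset)
          f_start <- cfg$evoked_band[2] - 1 + cfg$class_freq_offsets[[cls]]
          phi0 <- stats::runif(1, 0, 2 * pi)
          gains <- realize_class_encoding(cfg$encoding_mode, ci, n_classes,
                                          n_regions, cfg$encoding_separation)
          jit <- pmax(0.2, 1 + stats::rnorm(n_regions, sd = cfg$amplitude_jitter_sd))
          sender <- evoked_chirp(ns, fs, cfg$stim_onset, dur, f_start,
                                 cfg$chirp_rate, cfg$chirp_time, phi0)
          for (r in seq_len(n_regions)) {
            w <- if (r == 1L) sender$signal else switch(cfg$coupling_kind,
              none = evoked_chirp(ns, fs, cfg$stim_onset, dur, f_start,
                                  cfg$chirp_rate, cfg$chirp_time,
                                  stats::runif(1, 0, 2 * pi))$signal,
              linear_lag = evoked_chirp(ns, fs, cfg$stim_onset, dur, f_start,
                                        cfg$chirp_rate, cfg$chirp_time,
                                        phi0 - cfg$coupling_lag)$signal,
              nonlinear = odd_transform(sender$signal, cfg$nonlinearity))
            x[r, ] <- x[r, ] + cfg$snr * gains[r] * jit[r] * w
          }
        }
        x
      })
      data[, (sweep - 1L) * ns + seq_len(ns)] <- block
      onsets[sweep] <- (sweep - 1L) * ns + round(cfg$stim_onset * fs) + 1L
      classes_out[sweep] <- cls
    }
  }
  rownames(data) <- cfg$regions
  rec <- list(data = data, fs = fs, channel_labels = cfg$regions,
              events = data.frame(onset = onsets, class = classes_out,
                                  stringsAsFactors = FALSE),
              sweep_samples = ns, seed = cfg$seed, config = cfg)
  class(rec) <- "lfp_recording"
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    stopf("recording contains non-finite samples")
  if (is.unsorted(rec$events$onset))
    stopf("events must be sorted by onset")
  if (any(rec$events$onset < 1 | rec$events$onset > ncol(rec$data)))
    stopf("event onsets outside the recording")
  invisible(rec)
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) (%s), %d samples @ %g Hz, %d events\n",
              nrow(x$data), paste(x$channel_labels, collapse = ", "),
              ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}
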