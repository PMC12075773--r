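#' Configuration for the synthetic multi-region LFP generator
#'
#' Builds and validates the parameter set describing one synthetic olfactory
#' LFP experiment: repeated 50 s sweeps with a 1 s odor (or water control)
#' stimulus at 10 s, recorded in three regions (olfactory bulb `OB` and the
#' telencephalic areas `Vv` and `Dp`) at 1 kHz.  Odor sweeps carry an
#' amplitude-enveloped narrow-band oscillation (default 5--10 Hz) whose
#' instantaneous frequency drifts downwards by about 2 Hz over the first 2 s,
#' on top of 1/f-like baseline noise with excess power below 7 Hz.
#'
#' @param n_trials_per_class trials per stimulus class (default 20).
#' @param classes character vector of class labels; the last one is taken as
#'   the no-odor control unless `control_class` says otherwise.  Default
#'   `c("AA","SE","BS","TW")`: amino-acid mix, skin extract, bile-salt mix,
#'   and trout-water control.
#' @param control_class label of the class that receives no evoked component.
#' @param sweep_duration,stim_onset,stim_duration sweep timing in seconds
#'   (defaults 50, 10, 1).
#' @param fs sampling rate in Hz (default 1000).
#' @param regions channel labels; first region is the sender for inter-region
#'   coupling.  Default `c("OB","Vv","Dp")`.
#' @param baseline_spectrum list with `pink_weight`, `lf_weight`, `lf_cutoff`
#'   (Hz): mixture of 1/f (pink) noise and a low-pass AR(1) component giving
#'   the prominent < 7 Hz baseline activity.
#' @param evoked_band Hz pair for the evoked oscillation (default `c(5, 10)`).
#' @param evoked_duration range (s) from which each trial's evoked duration is
#'   drawn uniformly (default `c(10, 15)`).
#' @param chirp_rate downward frequency drift in Hz/s during the first
#'   `chirp_time` seconds of the response (defaults 1 Hz/s over 2 s, i.e. a
#'   2 Hz decline after 2 s).
#' @param chirp_time seconds over which the drift is applied.
#' @param class_freq_offsets named numeric, Hz added to the evoked start
#'   frequency per class (default: bile salts `BS` 1 Hz above the others).
#' @param coupling_kind one of `"none"`, `"linear_lag"`, `"nonlinear"`; how
#'   receiver regions relate to the sender's evoked component.
#' @param coupling_lag radians, constant cross-phase for `linear_lag`.
#' @param nonlinearity list describing the monotone odd transform used for
#'   `coupling_kind = "nonlinear"`; see [odd_transform()].
#' @param encoding_mode one of `"redundant"`, `"synergistic"`,
#'   `"independent"`: how class information is written into per-region evoked
#'   amplitudes; see [realize_class_encoding()].
#' @param encoding_separation relative amplitude separation between class
#'   gains (0 disables class-amplitude information).
#' @param snr evoked amplitude as a multiple of the baseline-noise SD.
#' @param amplitude_jitter_sd per-trial multiplicative amplitude jitter SD
#'   (trend-free, so trial amplitudes stay stationary across repetitions).
#' @param seed integer master seed; one child seed is derived per sweep so
#'   subsets of trials can be regenerated reproducibly.
#'
#' @return An object of class `synth_config` (validated named list).
#' @seealso [generate_recording()]
#' @export
synth_config <- function(n_trials_per_class = 20,
                         classes = c("AA", "SE", "BS", "TW"),
                         control_class = "TW",
                         sweep_duration = 50,
                         stim_onset = 10,
                         stim_duration = 1,
                         fs = 1000,
                         regions = c("OB", "Vv", "Dp"),
                         baseline_spectrum = list(pink_weight = 1,
                                                  lf_weight = 1.5,
                                                  lf_cutoff = 3),
                         evoked_band = c(5, 10),
                         evoked_duration = c(10, 15),
                         chirp_rate = 1,
                         chirp_time = 2,
                         class_freq_offsets = c(AA = 0, SE = 0.3, BS = 1, TW = 0),
                         coupling_kind = c("none", "linear_lag", "nonlinear"),
                         coupling_lag = pi / 2,
                         nonlinearity = list(type = "tanh", gain = 3),
                         encoding_mode = c("independent", "redundant", "synergistic"),
                         encoding_separation = 0.4,
                         snr = 2,
                         amplitude_jitter_sd = 0.1,
                         seed = 1L) {
  coupling_kind <- match.arg(coupling_kind)
  encoding_mode <- match.arg(encoding_mode)

  if (!is_count(n_trials_per_class) || n_trials_per_class < 2)
    stopf("n_trials_per_class must be an integer >= 2")
  if (length(classes) < 2 || anyDuplicated(classes))
    stopf("need >= 2 distinct class labels")
  if (!control_class %in% classes)
    stopf("control_class '%s' is not among classes", control_class)
  if (!is_num1(sweep_duration) || !is_num1(stim_onset) || !is_num1(stim_duration) ||
      sweep_duration <= 0 || stim_onset <= 0 || stim_duration <= 0)
    stopf("all durations must be positive scalars")
  if (stim_onset + stim_duration >= sweep_duration)
    stopf("stim_onset + stim_duration must be < sweep_duration")
  if (!is_num1(fs) || fs <= 0) stopf("fs must be a positive scalar")
  if (length(evoked_band) != 2 || evoked_band[1] <= 0 ||
      evoked_band[1] >= evoked_band[2])
    stopf("evoked_band must be an increasing positive Hz pair")
  if (evoked_band[2] + max(class_freq_offsets) >= fs / 2)
    stopf("evoked band exceeds the Nyquist frequency %g Hz", fs / 2)
  if (length(evoked_duration) != 2 || evoked_duration[1] <= 0 ||
      evoked_duration[1] > evoked_duration[2])
    stopf("evoked_duration must be a nondecreasing positive pair")
  if (!all(classes %in% names(class_freq_offsets))) {
    missing_cls <- setdiff(classes, names(class_freq_offsets))
    off <- stats::setNames(rep(0, length(missing_cls)), missing_cls)
    class_freq_offsets <- c(class_freq_offsets, off)
  }
  if (!is_num1(snr) || snr < 0) stopf("snr must be a nonnegative scalar")
  if (length(regions) < 1 || anyDuplicated(regions))
    stopf("regions must be distinct labels")

  cfg <- list(n_trials_per_class = as.integer(n_trials_per_class),
              classes = classes, control_class = control_class,
              sweep_duration = sweep_duration, stim_onset = stim_onset,
              stim_duration = stim_duration, fs = fs, regions = regions,
              baseline_spectrum = baseline_spectrum,
              evoked_band = evoked_band, evoked_duration = evoked_duration,
              chirp_rate = chirp_rate, chirp_time = chirp_time,
              class_freq_offsets = class_freq_offsets,
              coupling_kind = coupling_kind, coupling_lag = coupling_lag,
              nonlinearity = nonlinearity, encoding_mode = encoding_mode,
              encoding_separation = encoding_separation,
              snr = snr, amplitude_jitter_sd = amplitude_jitter_sd,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d classes (%s; control %s) x %d trials, %g s sweeps @ %g Hz\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$control_class, x$n_trials_per_class, x$sweep_duration, x$fs))
  cat(sprintf("  stimulus at %g s for %g s; evoked %g-%g Hz, chirp -%g Hz/s over %g s\n",
              x$stim_onset, x$stim_duration, x$evoked_band[1], x$evoked_band[2],
              x$chirp_rate, x$chirp_time))
  cat(sprintf("  coupling %s, encoding %s, snr %g, seed %d\n",
              x$coupling_kind, x$encoding_mode, x$snr, x$seed))
  invisible(x)
}
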