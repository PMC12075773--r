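---
title: "Linear and nonlinear connectivity measures for olfactory LFP recordings"
author: "olfconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and nonlinear connectivity measures for olfactory LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfconn)
```

## The scientific problem

Odor identity in the teleost brain is carried by distributed activity across
the olfactory bulb (OB) and telencephalic targets (the ventral nucleus of the
ventral telencephalon, Vv, and the dorsal posterior zone, Dp).  A central
question is *what kind* of inter-regional interaction carries that
information: classical oscillatory synchronization within a frequency band
(measured by coherence and phase-lag indices), or nonlinear interactions
visible only to information-theoretic measures (weighted symbolic mutual
information, co-information).  `olfconn` implements both families of measures
over a common preprocessing chain, a spectral decoding stage with
cluster-based permutation inference, and a synthetic multi-region LFP
generator that serves as the reference input for every stage.

## The synthetic generator

Raw recordings from this preparation are not publicly deposited, so the
package ships a generator (`synth_config()`, `generate_recording()`)
emulating the structure of the experiment: repeated 50 s sweeps at 1 kHz
with a 1 s stimulus at 10 s, 20 trials per stimulus class, and four classes
(amino-acid mix `AA`, skin extract `SE`, bile-salt mix `BS`, and the
trout-water control `TW`).  Its components:

* **Baseline noise** — a pink-noise plus low-pass AR(1) mixture, normalized
  to unit variance.  The AR cutoff (3 Hz) and mixing weights give the
  prominent sub-7 Hz background typical of these recordings with only three
  parameters.
* **Evoked response** — an amplitude-enveloped chirp (raised-cosine onset of
  0.5 s and offset of 1 s) lasting 10–15 s (uniform per trial), whose
  instantaneous frequency starts near the top of the 5–10 Hz evoked band and
  declines at 1 Hz/s over the first 2 s — i.e. a ~2 Hz downward drift after
  2 s.  Class-specific start-frequency offsets (bile salts ~1 Hz above the
  others) mimic the class differences seen in peak-frequency analyses.
  A trend-free multiplicative jitter (SD 0.1 by default) models inter-trial
  amplitude variability; since no quantitative value is reported for the
  real preparation this is an exposed free parameter, chosen to be small
  relative to the evoked amplitude.
* **Inter-region coupling** (`realize_coupling()`) — the first region (OB)
  is the sender.  `none` gives each region an independent-phase realization;
  `linear_lag` re-synthesizes the receiver chirp at a constant phase offset
  (default π/2); `nonlinear` passes the sender waveform through a monotone
  odd transform (tanh soft clipping by default) at **zero lag**, plus
  independent receiver noise.
* **Class encoding** (`realize_class_encoding()`) — multiplicative
  evoked-amplitude gains per region: one shared class gain (`redundant`),
  per-region rotated gain maps (`independent`), or an XOR pairing in which
  the class only fixes whether the first two regions' gains agree
  (`synergistic`), so each region alone is uninformative.

One master seed drives a per-sweep seed sequence, making recordings
bit-reproducible and letting trial subsets be regenerated.

### Why zero lag for the nonlinear mode

The package's central qualitative claim — ordinal-pattern information
sharing detects nonlinear coupling that phase metrics miss — is realized
geometrically.  wPLI discards interactions with zero (or π) phase lag by
construction, because those are indistinguishable from volume conduction of
a common source.  An instantaneous monotone odd transform of the sender
creates exactly such a zero-lag relationship: the imaginary cross-spectrum
is symmetric around zero and wPLI stays at its noise floor.  wSMI, in turn,
weights out *identical* and *opposite* symbol pairs (its own common-source
guard); the independent receiver noise perturbs sample ranks enough that
the dependence spills into neighboring ordinal patterns, which wSMI counts.
Both estimators therefore apply their own spurious-coupling defenses, and
only wSMI sees the interaction — the dissociation is a property of the
measures, not of a tuned simulation.

### What the generator does not emulate

No respiration or sniffing artifacts (absent in this preparation by
design), no biophysical circuit dynamics, no electrode drift or line noise,
and no cross-frequency structure beyond what the odd transform induces.
Passing tests on synthetic data therefore demonstrate estimator
correctness and the direction of the designed effects, not performance on
all features of real recordings.

## Preprocessing

`lowpass_downsample()` mirrors an acquisition chain: a causal 3-pole
Butterworth low-pass at 50 Hz followed by anti-aliased polyphase resampling
to 200 Hz (the Butterworth alone rolls off too slowly for a 5× decimation,
hence the additional FIR).  `epoch()` cuts stimulus-locked trials
(default −10 to +10 s) without resampling, so concatenating epochs
reproduces the source samples exactly.  `bandpass_zero_phase()` is the
second, analysis-side filtering context: an even-order symmetric FIR
applied by centered convolution on a reflection-padded signal, giving
exactly zero group delay; the default order targets a transition width
comparable to the band width (stopband > 40 dB an octave out).  The FIR
order is exposed because no canonical value exists for the 1 Hz-wide bins;
the half-open convention `[lo, hi)` makes the 6–10 Hz analysis bins
[6,7), [7,8), [8,9), [9,10).

## Spectra and scaleograms

`welch_spectrum()` uses 500-sample windows with 350-sample overlap (Hann
taper, mean detrend, density scaling so the integrated PSD matches the
variance).  Baseline handling follows the subtraction convention: the
average spectrum of the 10 s before the stimulus is subtracted from the
10 s after (`baseline_subtract()`), so net spectra may be negative.

`cwt_scaleogram()` implements the complex Morlet wavelet including its
zero-mean correction terms,

$$\psi(t) = c_\sigma\, \pi^{-1/4} e^{-t^2/2}\,\big(e^{i\sigma t} - e^{-\sigma^2/2}\big),$$

with σ = 5, evaluated in the frequency domain (exact, fast; edge effects
confined to a cone of influence of width ~σ/(2πf)).  The printed 1/s
prefactor of the transform is kept as written.  Scales map to frequencies
via the wavelet center frequency, `s = σ/(2πf)`; the familiar approximate
relation `T ~ s/σ` differs from this by the 2π constant, and z-scored
outputs are invariant to the choice.  `zscore_map()` normalizes each
frequency row by its baseline mean and SD; `peak_frequency_trace()`
reports the across-experiment mean peak frequency only at times where more
than half of the experiments exceed z = 5 somewhere in 5–20 Hz.

## Coherence

`coherence_spectrum()` computes magnitude-squared coherence from Welch
cross- and auto-spectra, pooling segments across trials before averaging
(trials are 10 s; 500 samples at 200 Hz is 2.5 s, so pooling is what makes
the estimate stable).  The Hann taper is a package choice — no taper is
canonical here — and is exposed structurally rather than as an option.
Coherence from a single segment is identically 1, so fewer than two
segments is an error.  Baseline subtraction (pre-stimulus coherence) gives
values in [−1, 1].

## Phase synchronization

`analytic_signal()` forms the Hilbert analytic signal per trial and
channel (FFT one-sided-spectrum method).  The cross-term
`S_xy = ξ_x ξ_y*` feeds

* `pli_window()`: `|Σ sgn Im S| / n`,
* `wpli_window()`: `|Σ |Im S| sgn Im S| / Σ |Im S|`,

pooled over trials *and* within-window samples (the index in the defining
sums ranges over "time point or trial", and both are pooled here — this is
documented because other implementations pool only trials).  Perfectly
zero-lag data zero every imaginary part; the estimators then return 0 with
a `degenerate` flag, the interpretation being that zero-lag data carry no
lag-asymmetry evidence.  `wpli_timecourse()` evaluates 1 Hz bins across
6–10 Hz, averages bins into one band trace (figures report a single
6–10 Hz trace), slides a 500 ms window at a 2 ms step — steps below one
sample at the working rate are rounded up to one sample — and z-scores
against the 1 s pre-stimulus baseline.  The spectral baseline is 10 s but
the wPLI baseline is 1 s; both are kept as separate configuration fields
rather than harmonized.

## Weighted symbolic mutual information

`symbolize()` encodes the rank ordering of k = 3 samples spaced τ apart
(6 symbols), ties broken by temporal order so the transform is
deterministic on quantized data.  τ is specified in milliseconds of the
1 kHz acquisition convention — the frequency-sensitivity relation
`f = 1000/(τ·k)` uses 1000 as the ms→s conversion — and converted to
samples at the working rate (`wsmi_tau_samples()`: τ = 32 ms is 6 samples
at 200 Hz, targeting ~6–10 Hz).  `build_weights()` zeroes identical and
opposite symbol pairs; `wsmi_value()` evaluates the weighted MI normalized
by log k!, natural logs throughout (any consistent base cancels).

Two estimator properties deserve note.  First, wSMI is invariant under any
strictly monotone transform of either signal — the nonlinearity-robustness
property the measure exists for.  Second, because the identical/opposite
cells are excluded, the weighted sum is *not* a full KL divergence and can
take small negative values on near-independent data (and on purely
common-source data, where the exclusion is doing its job); a signal paired
with itself or its negation gives exactly 0, and the normalization bounds
the value above by 1.  `wsmi_timecourse()` pools the joint symbol
distribution across trials and within-window positions (a symbol belongs
to a window when all its samples do), 500 ms windows, 2 ms step (rounded
to ≥ 1 sample).  Whether such traces should additionally be baseline
z-scored is not settled; both raw and z-scored traces are returned.

## Co-information

`gcmi_discrete()` rank-normalizes each variable to standard normal
quantiles (average ranks for ties, then the deterministic `r/(n+1)`
quantile map) and computes MI with the discrete class from
class-conditional Gaussian entropies with an analytic small-sample bias
correction (ψ-function terms), in bits.  Exactly collinear columns (e.g. a
duplicated region) are reduced to an independent basis before the
entropies, so duplication adds no spurious information.  The estimator is
exact for Gaussian class-conditional data at moderate effect sizes; under
complete class separation it saturates below the discrete ceiling
(~0.73 bits for two balanced classes) because the pooled ranks become
class-conditional half-normals — a documented property of the
copula-plus-Gaussian model, not an implementation error.

`coinformation()` combines `co-I = I(X;S) + I(Y;S) − I(X,Y;S)` per time
point from unfloored MI terms (flooring would bias the sign); positive
values mean redundant class information across regions, negative values
synergy.  `coinfo_pipeline()` chains band-pass (6–10 Hz) → Hilbert →
squared envelope → optional 500 ms moving-average smoothing (single-sample
MI at ~20 trials per class is high-variance; both smoothed and unsmoothed
paths exist) → co-I for a chosen class pair, and reports the post- versus
pre-stimulus contrast.

## Spectral decoding

`tf_features()` builds single-trial Morlet power features (default
1–40 Hz, 0–10 s, decimated in time).  `balance_by_undersampling()`
randomly reduces all classes to the smallest count.  `decode_multiclass()`
trains a linear discriminant with a shrinkage-regularized pooled
covariance (`(1−λ)S + λ·mean(diag S)·I`; λ = 0.05) under stratified
10-fold cross-validation.  Shrinkage matters because single-pixel feature
matrices with 1–3 dimensions are routinely ill-conditioned.  Performance
is the macro-averaged one-vs-rest AUC of the *softmax posterior* scores —
raw linear scores share a monotone trend across ordered classes that would
corrupt the ranking for middle classes — averaged across folds, against
the 0.5 chance level.  Whether decoding should use raw or z-scored power
is not settled; features are raw power by default.

`cluster_permutation_test()` runs pixel-wise two-sided t-tests across
subjects against chance, forms 4-connected clusters above the |t| quantile
at two-sided p = 0.05 (subjects − 1 df), scores clusters by summed t, and
compares them to the permutation null of the maximum cluster mass under
subject-wise sign flipping (default 1000 iterations).  "Subjects" in
synthetic cohorts are independent generator seeds (default 12, within the
11–14 experiments per condition typical of such datasets).

## Problem sizes used by the shipped tests

The test suite exercises every stage at sizes chosen to make the
statistical assertions well-powered while keeping a full run comfortably
interactive: estimator endpoint checks use 100–1000 constructed trials;
the wSMI/wPLI dissociation uses 100 paired simulations of 20 trials each;
co-information sign calibration uses 100 runs at 20 trials per class and
gain separation 0.5; decoder null calibration uses 200 repetitions of
8-subject, 10 × 50 null maps with 200 permutations; and the end-to-end
cohort uses 12 animals, 4 classes × 10 trials, 16 s sweeps, with decoding
on a 2–20 Hz grid.  The same code paths run unchanged at the full
experimental geometry (50 s sweeps, 20 trials, 1–40 Hz).

## Known limitations

* The generator's evoked component is a deterministic chirp with random
  phase; real responses have richer within-band structure, so absolute
  wSMI/co-I magnitudes are not comparable to recordings.
* Group statistics beyond the cluster permutation test (Kruskal–Wallis,
  post-hoc contrasts) are deliberately out of scope; `export_summary()`
  produces the long-format per-animal table those tests consume.
* Single-trial co-I at ~20 trials per class is noisy; the smoothing window
  trades temporal resolution for variance.
* The `independent` encoding mode assigns deterministic per-region gain
  maps, which still renders each region individually informative; true
  zero-redundancy encodings require the zero-separation configuration.
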