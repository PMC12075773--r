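# olfconn

Linear and nonlinear connectivity analysis of multi-region olfactory local
field potentials (LFPs).

## What problem this solves

In the fish olfactory system, odor information travels from the olfactory
bulb (OB) to telencephalic targets (Vv, Dp) on top of a prominent 5–10 Hz
odor-evoked oscillation.  Whether odorant *identity* is carried by classical
same-frequency synchronization between these regions, or by nonlinear
interactions that phase- and coherence-based measures cannot see, is a
question about the *measures* as much as the biology.  `olfconn` provides,
over one common preprocessing chain:

- **Spectral characterization** — Welch spectra (500-sample windows,
  350-sample overlap) with pre-stimulus baseline subtraction; complex Morlet
  (σ = 5) scaleograms `|W(t,s)|²` z-scored to baseline; peak-frequency
  trajectories gated by a z > 5 criterion.
- **Linear connectivity** — magnitude-squared coherence
  `C_xy = |⟨P_x* P_y⟩|² / (⟨|P_x|²⟩⟨|P_y|²⟩)`, and the phase-lag indices
  from Hilbert analytic signals,
  `PLI = |Σ sgn Im S_xy| / n` and
  `wPLI = |Σ |Im S_xy| sgn Im S_xy| / Σ |Im S_xy|`,
  in sliding 500 ms windows over 1 Hz bins spanning 6–10 Hz.
- **Nonlinear connectivity** — weighted symbolic mutual information:
  signals are symbolized by the rank order of k = 3 samples spaced τ apart
  (τ = 32 ms targets ~6–10 Hz via `f = 1000/(τ·k)`), and
  `wSMI = (1/log k!) Σ w(x,y) p(x,y) log[p(x,y)/(p(x)p(y))]`
  with identical and opposite symbol pairs weighted out.
- **Redundancy/synergy** — Gaussian-copula mutual information between
  6–10 Hz band power and stimulus class, combined as
  `co-I(X;Y;S) = I(X;S) + I(Y;S) − I(X,Y;S)` (positive = redundant,
  negative = synergistic).
- **Spectral decoding** — multiclass shrinkage-LDA on single-trial
  time–frequency power (multivariate across regions or univariate), 10-fold
  stratified CV, macro one-vs-rest AUC, and group-level cluster-based
  permutation tests (max-cluster-mass null under subject sign flipping).
- **A synthetic LFP generator** — 50 s sweeps, stimulus at 10 s, 20 trials
  per class, 1/f-plus-low-frequency baseline noise, an evoked 5–10 Hz chirp
  declining ~2 Hz over 2 s, configurable inter-region coupling
  (none / constant-lag / monotone-odd nonlinear at zero lag) and class
  encoding (redundant / independent / synergistic XOR), bit-reproducible
  from one seed.

## Worked example

```r
library(olfconn)

cfg <- synth_config(n_trials_per_class = 8, classes = c("AA", "BS", "TW"),
                    control_class = "TW",
                    class_freq_offsets = c(AA = 0, BS = 1, TW = 0),
                    sweep_duration = 16, stim_onset = 5, fs = 1000,
                    evoked_duration = c(6, 8),
                    coupling_kind = "nonlinear", encoding_mode = "redundant",
                    seed = 7)
rec <- generate_recording(cfg)
rec <- lowpass_downsample(rec, cutoff = 50, order = 3, target_fs = 200)
ep  <- epoch(rec, window = c(-4, 8), baseline = c(-4, 0))

odor <- epoch_subset(ep, ep$labels == "AA")
ctrl <- epoch_subset(ep, ep$labels == "TW")

spec <- baseline_subtract(
  welch_spectrum(ep, "OB", interval = "post", trials = ep$labels == "AA"),
  welch_spectrum(ep, "OB", interval = "pre",  trials = ep$labels == "AA"))
spec$freqs[which.max(spec$power)]

timecourse_mean(wsmi_timecourse(odor, c("OB", "Vv"), step_s = 0.05))
timecourse_mean(wsmi_timecourse(ctrl, c("OB", "Vv"), step_s = 0.05))
timecourse_mean(wpli_timecourse(odor, c("OB", "Vv"), step_s = 0.05))
timecourse_mean(wpli_timecourse(ctrl, c("OB", "Vv"), step_s = 0.05))

coinfo_pipeline(ep, c("OB", "Vv"), c("AA", "BS"), post = c(1, 5))
```

This prints (numbers from the run above):

```
evoked peak: 7.2 Hz
wSMI OB-Vv, 1-5 s mean: odor 0.0435 vs control 0.0115
wPLI OB-Vv, 1-5 s mean: odor 0.3620 vs control 0.3859
co-I OB-Vv (AA vs BS): post 0.431 bits, pre -0.017 bits
```

Read: the evoked oscillation peaks inside the 5–10 Hz band; with nonlinear
(zero-lag, monotone-odd) inter-region coupling, the odor condition raises
wSMI nearly fourfold over control while wPLI shows no excess at all — the
dissociation the nonlinear measures exist for; and the shared class gain
produces strongly positive post-stimulus co-information (redundant coding)
against a pre-stimulus level of ~0.

For whole-cohort runs (many seeded "animals", all measures, decoding, and
a long-format summary table for external statistics) see `run_pipeline()`
and `export_summary()`, and the methods vignette
(`vignettes/olfconn-methods.Rmd`) for the models, conventions and parameter
choices.

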