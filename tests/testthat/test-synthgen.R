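test_that("configuration invariants are enforced", {
  expect_error(synth_config(stim_onset = 49, sweep_duration = 50), "sweep_duration")
  expect_error(synth_config(n_trials_per_class = 1), ">= 2")
  expect_error(synth_config(evoked_band = c(10, 5)), "evoked_band")
  expect_error(synth_config(fs = 15), "Nyquist")
  expect_error(synth_config(coupling_kind = "magic"))
  expect_s3_class(small_config(), "synth_config")
})

test_that("identical config and seed give a bit-identical recording", {
  cfg <- small_config(seed = 7)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  r3 <- generate_recording(small_config(seed = 8))
  expect_false(identical(r1$data, r3$data))
})

test_that("recordings are finite with sorted in-bounds events", {
  rec <- generate_recording(small_config(seed = 3))
  expect_true(all(is.finite(rec$data)))
  expect_false(is.unsorted(rec$events$onset))
  expect_true(all(rec$events$onset + 5 * rec$fs <= ncol(rec$data)))
  expect_equal(nrow(rec$events), 3 * 4)
})

test_that("snr 0 and control sweeps carry no evoked band power", {
  rec <- generate_recording(small_config(seed = 5, snr = 0))
  ep <- epoch(rec, c(-5, 10), c(-5, 0))
  for (r in 1:3) {
    d <- baseline_subtract(
      welch_spectrum(ep, r, interval = c(0, 10)),
      welch_spectrum(ep, r, interval = c(-5, 0)))
    band <- d$freqs >= 5 & d$freqs <= 10
    full <- welch_spectrum(ep, r, interval = c(0, 10))
    expect_lt(abs(sum(d$power[band])) / sum(full$power), 0.2)
  }
})

test_that("odor sweeps put the baseline-subtracted spectral peak in the evoked band", {
  rec <- generate_recording(small_config(seed = 11))
  ep <- epoch(rec, c(-5, 10), c(-5, 0))
  for (r in 1:3) {
    odor <- ep$labels == "AA"
    d <- baseline_subtract(
      welch_spectrum(ep, r, interval = c(0, 10), trials = odor),
      welch_spectrum(ep, r, interval = c(-5, 0), trials = odor))
    sel <- d$freqs >= 1 & d$freqs <= 40
    peak <- d$freqs[sel][which.max(d$power[sel])]
    expect_gte(peak, 5); expect_lte(peak, 10)
    ## control class: no systematic change
    ctrl <- ep$labels == "TW"
    dc <- baseline_subtract(
      welch_spectrum(ep, r, interval = c(0, 10), trials = ctrl),
      welch_spectrum(ep, r, interval = c(-5, 0), trials = ctrl))
    expect_lt(max(abs(dc$power[sel])), max(d$power[sel]) / 2)
  }
})

test_that("evoked amplitude is stationary across trial repetitions", {
  cfg <- small_config(seed = 13, n_trials_per_class = 10,
                      classes = c("AA", "TW"),
                      class_freq_offsets = c(AA = 0, TW = 0))
  rec <- generate_recording(cfg)
  ep <- epoch(rec, c(-2, 6), c(-2, 0))
  odor <- which(ep$labels == "AA")
  bp <- bandpass_zero_phase(epoch_subset(ep, odor), 5, 11)
  amp <- vapply(seq_along(odor), function(i)
    max(abs(bp$data[i, 1, ])), numeric(1))
  fit <- summary(lm(amp ~ seq_along(amp)))
  expect_gt(fit$coefficients[2, 4], 0.05)  # no trend over repetitions
})

test_that("linear_lag coupling realizes the configured constant cross-phase", {
  cfg <- small_config(seed = 21, coupling_kind = "linear_lag",
                      coupling_lag = pi / 2, snr = 50,
                      amplitude_jitter_sd = 0)
  rec <- generate_recording(cfg)
  ep <- epoch(rec, c(-1, 5), c(-1, 0))
  odor <- ep$labels == "AA"
  bp <- bandpass_zero_phase(epoch_subset(ep, odor), 5, 11)
  as <- analytic_signal(bp)
  ## steady-state part of the response, away from ramps
  idx <- which(epoch_times(ep) > 1.5 & epoch_times(ep) < 4)
  dphi <- Arg(as$xi[, 1, idx] * Conj(as$xi[, 2, idx]))
  circ_mean <- Arg(mean(exp(1i * dphi)))
  expect_lt(abs(circ_mean - pi / 2), 0.15)
})

test_that("phase-randomized surrogate coupling preserves the spectrum", {
  set.seed(1)
  x <- as.numeric(stats::filter(rnorm(2048), rep(1, 5) / 5, sides = 2))
  x[is.na(x)] <- 0
  y <- realize_coupling(x, "none", seed = 4)
  px <- Mod(fft(x))^2
  py <- Mod(fft(y))^2
  expect_equal(px[2:1024], py[2:1024], tolerance = 1e-6)
  expect_gt(max(abs(x - y)), 0.1)  # but it is a different realization
})

test_that("odd transforms are monotone and preserve symbol sequences", {
  set.seed(2)
  x <- rnorm(300)
  for (spec in list(list(type = "tanh", gain = 3),
                    list(type = "power", exponent = 1 / 3))) {
    y <- odd_transform(x, spec)
    expect_true(all(diff(y[order(x)]) >= 0))
    expect_identical(symbolize(x, 3, 5), symbolize(y, 3, 5))
  }
  expect_error(odd_transform(x, list(type = "bogus")), "unknown")
})

test_that("class encoding gains realize redundant / independent / synergistic structure", {
  g1 <- realize_class_encoding("redundant", 1, 4, 3, 0.4)
  g4 <- realize_class_encoding("redundant", 4, 4, 3, 0.4)
  expect_equal(g1, rep(0.6, 3))
  expect_equal(g4, rep(1.4, 3))
  gi <- realize_class_encoding("independent", 2, 4, 3, 0.4)
  expect_equal(length(unique(gi)), 3)  # regions use different mappings
  set.seed(9)
  gs <- t(replicate(400, realize_class_encoding("synergistic", 2, 4, 2, 0.4)))
  ga <- t(replicate(400, realize_class_encoding("synergistic", 1, 4, 2, 0.4)))
  ## even class: gains agree; odd class: gains disagree; marginals balanced
  expect_true(all(gs[, 1] == gs[, 2]))
  expect_true(all(ga[, 1] != ga[, 2]))
  expect_gt(mean(gs[, 1] > 1), 0.4); expect_lt(mean(gs[, 1] > 1), 0.6)
  expect_error(realize_class_encoding("redundant", 9, 4, 3), "out of range")
})

test_that("recordings round-trip through the text serialization", {
  rec <- generate_recording(small_config(seed = 2, n_trials_per_class = 2,
                                         sweep_duration = 8, stim_onset = 3,
                                         evoked_duration = c(2, 3), fs = 200))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$events$onset, rec$events$onset)
  expect_equal(back$events$class, rec$events$class)
  expect_equal(back$fs, rec$fs)
  unlink(c(path, paste0(path, ".json")))
})
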