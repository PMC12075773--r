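## brute-force oracle: weighted MI from an explicit double loop over the
## joint histogram of two symbol streams
brute_wsmi <- function(sx, sy, k, w = NULL) {
  nk <- factorial(k)
  if (is.null(w)) w <- build_weights(k)
  n <- length(sx)
  total <- 0
  for (a in seq_len(nk)) for (b in seq_len(nk)) {
    pab <- sum(sx == a & sy == b) / n
    if (pab > 0 && w[a, b] > 0) {
      pa <- sum(sx == a) / n; pb <- sum(sy == b) / n
      total <- total + pab * log(pab / (pa * pb))
    }
  }
  total / log(nk)
}

test_that("symbolization encodes rank patterns, ties, and sign flips as specified", {
  ## (1, 3, 2): low, high, mid
  code_lhm <- symbolize(c(1, 3, 2), 3, 1)
  expect_length(code_lhm, 1)
  ## monotone transforms leave symbols unchanged
  expect_identical(symbolize(c(10, 300, 20), 3, 1), code_lhm)
  ## all six orderings of distinct values give six distinct codes
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  codes <- vapply(perms, symbolize, integer(1), k = 3, tau = 1)
  expect_equal(sort(codes), 1:6)
  ## strictly increasing ramp: one repeated "ascending" symbol
  ramp <- symbolize(seq(0.1, 10, length.out = 50), 3, 4)
  expect_equal(length(unique(ramp)), 1)
  expect_identical(unique(ramp), symbolize(c(1, 2, 3), 3, 1))
  ## sign flip maps every symbol to its opposite partner, consistently
  set.seed(30)
  x <- rnorm(200)
  s_pos <- symbolize(x, 3, 7)
  s_neg <- symbolize(-x, 3, 7)
  expect_true(all(s_pos != s_neg))
  expect_equal(length(unique(paste(s_pos, s_neg))), 6)  # a bijection
  ## ties resolve by temporal order: earlier sample ranks lower
  expect_identical(symbolize(c(2, 2, 1), 3, 1), symbolize(c(2, 3, 1), 3, 1))
  expect_error(symbolize(c(1, 2), 3, 5), "too short")
})

test_that("the weight matrix zeroes identical and opposite symbol pairs only", {
  w <- build_weights(3)
  expect_equal(dim(w), c(6, 6))
  expect_equal(sum(w == 0), 12)  # 6 diagonal + 6 opposite
  expect_equal(sum(w == 1), 24)
  expect_true(all(diag(w) == 0))
  expect_identical(w, t(w))
  ## brute-force enumeration oracle: opposite = code of the negated pattern
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    a <- symbolize(p, 3, 1); b <- symbolize(-p, 3, 1)
    expect_equal(w[a, b], 0)
  }
  ## k = 2 degenerates to the all-zero matrix
  expect_true(all(build_weights(2) == 0))
})

test_that("wSMI of a signal with itself and with its negation is exactly zero", {
  set.seed(31)
  x <- rnorm(1000)
  sx <- symbolize(x, 3, 6)
  expect_identical(wsmi_value(sx, sx), 0)
  expect_identical(wsmi_value(sx, symbolize(-x, 3, 6)), 0)
})

test_that("wSMI matches the brute-force plug-in evaluation on identical counts", {
  set.seed(32)
  for (rep in 1:5) {
    x <- rnorm(400); y <- 0.6 * x + 0.8 * rnorm(400)
    sx <- symbolize(x, 3, 5); sy <- symbolize(y, 3, 5)
    expect_equal(wsmi_value(sx, sy), brute_wsmi(sx, sy, 3), tolerance = 1e-12)
    ## unweighted variant equals the plain plug-in MI on the same counts
    expect_equal(wsmi_value(sx, sy, weighted = FALSE),
                 brute_wsmi(sx, sy, 3, w = matrix(1, 6, 6)), tolerance = 1e-12)
  }
})

test_that("independent streams give wSMI near zero, bias quantified against the plug-in MI", {
  set.seed(33)
  vals <- t(replicate(20, {
    sx <- symbolize(rnorm(3000), 3, 5)
    sy <- symbolize(rnorm(3000), 3, 5)
    c(w = wsmi_value(sx, sy), plug = wsmi_value(sx, sy, weighted = FALSE))
  }))
  ## the full plug-in MI has the classic positive finite-n bias ...
  expect_gt(mean(vals[, "plug"]), 0)
  expect_lt(mean(vals[, "plug"]), 0.01)
  ## ... the weighted variant (high-PMI diagonal excluded) stays near zero
  ## from either side, and below the plug-in bias level
  expect_lt(abs(mean(vals[, "w"])), 0.005)
  expect_true(all(abs(vals[, "w"]) < 0.02))
  expect_lt(mean(vals[, "w"]), mean(vals[, "plug"]))
})

test_that("wSMI is invariant under strictly monotone transforms of either signal", {
  set.seed(34)
  fs <- 200
  tv <- seq_len(6 * fs) / fs
  x <- cos(2 * pi * 8 * tv) + 0.5 * rnorm(length(tv))
  y <- odd_transform(x) + 0.5 * rnorm(length(tv))
  tau <- wsmi_tau_samples(32, fs)
  base <- wsmi_value(symbolize(x, 3, tau), symbolize(y, 3, tau))
  warped <- wsmi_value(symbolize(exp(x), 3, tau),
                       symbolize(y^3 + 2 * y, 3, tau))
  expect_identical(base, warped)
  expect_gt(base, 0.005)
})

test_that("tau tuned by f = 1000/(tau k) makes wSMI maximal for band-matched coupling", {
  set.seed(35)
  fs <- 200
  n <- 6 * fs
  tv <- seq_len(n) / fs
  wsmi_at <- function(f_couple, tau_ms) {
    tau <- wsmi_tau_samples(tau_ms, fs)
    v <- replicate(12, {
      x <- cos(2 * pi * f_couple * tv + runif(1, 0, 2 * pi)) + 0.4 * rnorm(n)
      y <- odd_transform(x) + 0.4 * rnorm(n)
      wsmi_value(symbolize(x, 3, tau), symbolize(y, 3, tau))
    })
    mean(v)
  }
  ## tau = 32 ms targets ~6-10 Hz: 8 Hz coupling must beat 30 Hz coupling
  expect_gt(wsmi_at(8, 32), 1.5 * wsmi_at(30, 32))
})

test_that("wSMI time courses rise after stimulus for nonlinear coupling but not for control", {
  cfg <- small_config(seed = 36, coupling_kind = "nonlinear",
                      n_trials_per_class = 6, classes = c("AA", "TW"),
                      class_freq_offsets = c(AA = 0, TW = 0))
  rec <- lowpass_downsample(generate_recording(cfg), 50, 3, 200)
  ep <- epoch(rec, c(-3, 6), c(-3, 0))
  tc_odor <- wsmi_timecourse(epoch_subset(ep, ep$labels == "AA"), c(1, 2),
                             step_s = 0.05)
  tc_ctrl <- wsmi_timecourse(epoch_subset(ep, ep$labels == "TW"), c(1, 2),
                             step_s = 0.05)
  expect_gt(timecourse_mean(tc_odor, c(1, 5), "raw"),
            timecourse_mean(tc_ctrl, c(1, 5), "raw") + 0.005)
  ## uncoupled control trace is flat near its own baseline level
  pre <- mean(tc_ctrl$raw[tc_ctrl$times < 0])
  post <- timecourse_mean(tc_ctrl, c(1, 5), "raw")
  expect_lt(abs(post - pre), 0.01)
  expect_error(wsmi_timecourse(ep, c(1, 2), window_s = 0.05), "symbol span")
})

test_that("richer odors (more spectral components) share more information", {
  set.seed(37)
  fs <- 200
  n <- 6 * fs
  tv <- seq_len(n) / fs
  ## a richer odor drives more shared narrow-band components (fixed
  ## per-component amplitude and receiver noise)
  wsmi_components <- function(n_comp) {
    freqs <- seq(6.5, 9.5, length.out = n_comp)
    v <- replicate(25, {
      shared <- rowSums(vapply(freqs, function(f)
        cos(2 * pi * f * tv + runif(1, 0, 2 * pi)), numeric(n)))
      x <- shared + rnorm(n)
      y <- odd_transform(shared) + rnorm(n)
      tau <- wsmi_tau_samples(32, fs)
      wsmi_value(symbolize(x, 3, tau), symbolize(y, 3, tau))
    })
    mean(v)
  }
  expect_gt(wsmi_components(3), wsmi_components(1))
})
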