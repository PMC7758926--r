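# Butterworth design, zero-phase filtering, snippet extraction

test_that("bandpass design is valid in-band and rejects bad edges", {
  spec <- design_bandpass(1, 47, 5, 200)
  # single-pass magnitude response at 24 Hz (mid-band) via the transfer fn
  hmag <- function(spec, f, fs) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(spec$b * z^(seq_along(spec$b) - 1)) /
          sum(spec$a * z^(seq_along(spec$a) - 1)))
  }
  expect_gte(hmag(spec, 24, 200), 0.99)
  expect_s3_class(design_bandpass(3, 8, 5, 200), "pges_filter")
  expect_error(design_bandpass(47, 1, 5, 200), class = "pges_argument_error")
  expect_error(design_bandpass(1, 120, 5, 200), class = "pges_argument_error")
  expect_error(design_bandpass(0, 47, 5, 200), class = "pges_argument_error")
})

test_that("forward-backward filtering has zero phase", {
  spec <- design_bandpass(1, 47, 5, 200)
  t <- seq_len(2000)
  pulse <- exp(-((t - 1000)^2) / (2 * 20^2))   # symmetric Gaussian pulse
  y <- filter_zero_phase(pulse, spec)
  expect_lte(abs(which.max(y) - 1000), 1)
})

test_that("passband tones pass and stopband tones are rejected (1-47 Hz)", {
  spec <- design_bandpass(1, 47, 5, 200)
  t <- (0:1999) / 200
  steady <- 501:1500                           # avoid edge transients
  amp <- function(f) {
    y <- filter_zero_phase(sin(2 * pi * f * t), spec)
    dft_amplitude(y[steady], f, 200)           # steady-state tone amplitude
  }
  a25 <- amp(25)
  expect_gte(a25, 0.97)
  expect_lte(a25, 1.0 + 1e-6)
  expect_lt(amp(60), 0.1)
})

test_that("slow-wave band filter passes 5 Hz and rejects 20 Hz and drift", {
  spec <- design_bandpass(3, 8, 5, 200)
  t <- (0:1999) / 200
  steady <- 501:1500
  y5 <- filter_zero_phase(sin(2 * pi * 5 * t), spec)
  expect_lt(abs(dft_amplitude(y5[steady], 5, 200) - 1), 0.05)
  y20 <- filter_zero_phase(sin(2 * pi * 20 * t), spec)
  expect_lt(dft_amplitude(y20[steady], 20, 200), 0.1)
  # a 1 Hz drift component is strongly attenuated relative to an
  # equal-power 5 Hz reference
  rms <- function(x) sqrt(mean(x^2))
  y1 <- filter_zero_phase(sin(2 * pi * 1 * t), spec)
  expect_lt(rms(y1[steady]), 0.2 * rms(y5[steady]))
})

test_that("filtering is linear and symmetric under time reversal", {
  spec <- design_bandpass(1, 47, 5, 200)
  set.seed(8)
  x <- rnorm(2000)
  y <- rnorm(2000)
  lhs <- filter_zero_phase(2 * x - 3 * y, spec)
  rhs <- 2 * filter_zero_phase(x, spec) - 3 * filter_zero_phase(y, spec)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
  # zero-phase symmetry: forward-then-backward equals its time-reversed
  # application away from the edge transients (which decay with the 1 Hz
  # pole; the edges themselves differ, as in any padded implementation)
  fwd <- filter_zero_phase(x, spec)
  bwd <- rev(filter_zero_phase(rev(x), spec))
  expect_lt(max(abs(fwd[801:1200] - bwd[801:1200])), 1e-2)
})

test_that("too-short series raise an argument error", {
  spec <- design_bandpass(1, 47, 5, 200)
  expect_error(filter_zero_phase(rnorm(20), spec),
               class = "pges_argument_error")
})

test_that("snippet denoising attenuates mains and keeps in-band activity", {
  core <- 200:1800                            # edge transients excluded
  rms <- function(x) sqrt(mean(x^2))
  # 50 Hz sits on the filter's shoulder: the squared 5th-order response
  # there is 0.27, so two-pass filtering leaves under 30% of the RMS;
  # 60 Hz is well into the stopband (squared response 0.014)
  mains50 <- sin_snippet(freqs = rep(50, 3))
  out50 <- denoise_snippet(mains50)
  expect_lt(rms(out50$samples[core, ]), 0.3 * rms(mains50$samples[core, ]))
  mains60 <- sin_snippet(freqs = rep(60, 3))
  out <- denoise_snippet(mains60)
  expect_lt(rms(out$samples[core, ]), 0.05 * rms(mains60$samples[core, ]))
  zero <- sin_snippet(freqs = rep(5, 2), amps = c(0, 0))
  expect_equal(denoise_snippet(zero)$samples, zero$samples)
  # 10 Hz activity survives within 5% RMS after edge trimming
  act <- sin_snippet(freqs = c(10, 10))
  outa <- denoise_snippet(act)
  err <- rms(outa$samples[core, 1] - act$samples[core, 1])
  expect_lt(err, 0.05 * rms(act$samples[core, 1]))
  expect_equal(outa$label, act$label)
  expect_equal(outa$fs, act$fs)
})

test_that("snippet positivity follows the open-interval rule", {
  x <- matrix(rnorm(40 * 200 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  rec <- recording(x, 200, patient_id = "P1", pges_end_s = 30)
  snips <- extract_snippets(rec, n_per_class = 20, rng_seed = 4)
  for (s in snips) {
    contains <- s$start_s < 30 && 30 < s$start_s + 10
    expect_equal(s$label, as.integer(contains))
    expect_equal(nrow(s$samples), 2000)
    expect_equal(ncol(s$samples), 2)
    # starts lie on the sample grid
    expect_equal(s$start_s * 200, round(s$start_s * 200))
  }
  # both classes in equal number when the recording admits them
  labels <- vapply(snips, function(s) s$label, integer(1))
  expect_equal(sum(labels == 1), 20)
  expect_equal(sum(labels == 0), 20)
})

test_that("snippet extraction is deterministic and boundary-exclusive", {
  x <- matrix(rnorm(40 * 200), ncol = 1, dimnames = list(NULL, "a"))
  rec <- recording(x, 200, pges_end_s = 30)
  s1 <- extract_snippets(rec, 5, rng_seed = 11)
  s2 <- extract_snippets(rec, 5, rng_seed = 11)
  expect_identical(vapply(s1, function(s) s$start_s, numeric(1)),
                   vapply(s2, function(s) s$start_s, numeric(1)))
  # a transition exactly on the window boundary is not contained: a 10-s
  # recording annotated at 10 s admits only the start-0 window -> negative
  edge <- recording(x[1:2000, , drop = FALSE], 200, pges_end_s = 10)
  snips <- extract_snippets(edge, 3, rng_seed = 2)
  expect_true(all(vapply(snips, function(s) s$label, integer(1)) == 0L))
})

test_that("unannotated and too-short recordings degrade gracefully", {
  x <- matrix(rnorm(40 * 200), ncol = 1, dimnames = list(NULL, "a"))
  rec <- recording(x, 200)                           # no annotation
  snips <- extract_snippets(rec, 5, rng_seed = 1)
  expect_true(all(vapply(snips, function(s) s$label, integer(1)) == 0L))
  short <- recording(x[1:400, , drop = FALSE], 200)
  expect_warning(out <- extract_snippets(short, 5, rng_seed = 1),
                 regexp = "shorter")
  expect_length(out, 0)
})
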