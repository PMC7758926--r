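# feature families: counts, oracle equivalence, invariances, guards

test_that("family and total feature counts match the construction formula", {
  s <- random_snippet(seed = 1)
  expect_length(correlation_features(denoise_snippet(s)), 45)
  expect_length(temporal_ratio_features(denoise_snippet(s)), 24)
  expect_length(lowfreq_temporal_ratio_features(s), 24)
  expect_length(lowfreq_signal_features(s), 22)
  expect_length(sliding_difference_features(s), 12)
  v <- extract_all(s)
  expect_length(v, 127)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_true(all(is.finite(v)))
  # general formula by name enumeration for k = 2..10 channels
  for (k in 2:10) {
    vk <- extract_all(s, channels = canonical_channels()[seq_len(k)])
    expect_length(vk, choose(k, 2) + 7 * k + 12)
    expect_false(anyDuplicated(names(vk)) > 0)
  }
  expect_error(extract_all(s, channels = "Fz"), class = "pges_argument_error")
  expect_error(extract_all(s, channels = c("Fz", "Qz")),
               class = "pges_argument_error")
})

test_that("correlation features match brute-force Pearson to 1e-10", {
  for (seed in 1:20) {
    s <- random_snippet(seed = seed, n_channels = 4)
    sd_ <- denoise_snippet(s)
    feats <- correlation_features(sd_)
    pairs <- combn(4, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      expect_lt(abs(feats[p] - pearson_brute(sd_$samples[, i],
                                             sd_$samples[, j])), 1e-10)
    }
  }
})

test_that("correlation features honor affine invariance and sign", {
  x <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  x[, 2] <- 3 * x[, 1] + 5
  s <- snippet(x, 200)
  expect_equal(unname(correlation_features(s)), 1.0)
  x[, 2] <- -x[, 1]
  expect_equal(unname(correlation_features(snippet(x, 200))), -1.0)
  # zero-variance channel resolves to 0
  x[, 2] <- 7
  expect_equal(unname(correlation_features(snippet(x, 200))), 0)
})

test_that("least-variance channel picks the minimum with index tie-break", {
  x <- cbind(a = rnorm(2000, sd = 2), b = rnorm(2000, sd = 1),
             c = rnorm(2000, sd = 3))
  expect_equal(least_variance_channel(snippet(x, 200)), 2)
  same <- cbind(a = rnorm(2000), b = 0, c = rnorm(2000))
  expect_equal(least_variance_channel(snippet(same, 200)), 2)
  ident <- cbind(a = rnorm(2000))
  expect_equal(least_variance_channel(snippet(cbind(a = ident[, 1],
                                                    b = ident[, 1]), 200)), 1)
})

test_that("temporal ratios are exact on constructed halves", {
  # identical halves: all ratios 1
  half <- matrix(rnorm(1000 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  s <- snippet(rbind(half, half), 200)
  v <- temporal_ratio_features(s)
  expect_equal(unname(v[c("tmr.a", "tmr.b", "tvr.a", "tvr.b")]),
               rep(1, 4))
  # last half scaled by 2 about the mean: variance ratio 4
  osc <- sin(2 * pi * 7 * (0:999) / 200)
  s2 <- snippet(cbind(a = c(osc, 2 * osc), b = rnorm(2000)), 200)
  v2 <- temporal_ratio_features(s2)
  expect_equal(unname(v2["tvr.a"]), 4, tolerance = 1e-10)
})

test_that("near-zero denominators resolve to the guard value 0", {
  # first half exactly zero mean and variance
  x <- cbind(a = c(rep(0, 1000), rnorm(1000)), b = rnorm(2000))
  v <- temporal_ratio_features(snippet(x, 200))
  expect_equal(unname(v["tmr.a"]), 0)
  expect_equal(unname(v["tvr.a"]), 0)
  # all-zero snippet: every slow-wave statistic and summary is 0/finite
  z <- snippet(matrix(0, 2000, 2, dimnames = list(NULL, c("a", "b"))), 200)
  lf <- lowfreq_signal_features(z)
  expect_true(all(lf == 0))
  expect_true(all(is.finite(extract_all(z))))
})

test_that("slow-wave ratio features see amplitude modulation", {
  # 5 Hz tone stepping from amplitude a to 2a at the midpoint
  t1 <- (0:999) / 200
  t2 <- (1000:1999) / 200
  x <- cbind(a = c(3 * sin(2 * pi * 5 * t1), 6 * sin(2 * pi * 5 * t2)),
             b = rnorm(2000, sd = 0.1))
  v <- lowfreq_temporal_ratio_features(snippet(x, 200))
  expect_equal(unname(v["lf_tvr.a"]), 4, tolerance = 0.1 * 4)
  # out-of-band content leaves near-zero slow-wave signal; guards keep
  # everything finite
  s20 <- sin_snippet(freqs = c(20, 20))
  v20 <- lowfreq_temporal_ratio_features(s20)
  expect_true(all(is.finite(v20)))
})

test_that("slow-wave variance of an in-band sinusoid is A^2/2", {
  a <- 12
  s <- sin_snippet(freqs = c(5, 5), amps = c(a, a))
  v <- lowfreq_signal_features(s)
  expect_equal(unname(v["lf_var.ch1"]), a^2 / 2, tolerance = 0.05 * a^2 / 2)
})

test_that("sliding difference matches a brute-force window scan", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(2000)
    expect_equal(pges:::sliding_max_diff(x), sliding_brute(x))
  }
  # linear ramp of slope m: every placement scores 625*m
  m <- 0.37
  expect_equal(pges:::sliding_max_diff(m * (0:1999)), 625 * m,
               tolerance = 1e-9)
  # constant channel scores 0
  expect_equal(pges:::sliding_max_diff(rep(4.2, 2000)), 0)
  expect_error(pges:::sliding_max_diff(rnorm(30)),
               class = "pges_argument_error")
})

test_that("channel scaling affects exactly the scale-covariant features", {
  s <- random_snippet(seed = 3)
  v0 <- extract_all(s)
  s2 <- s
  s2$samples[, "F7"] <- 2.5 * s2$samples[, "F7"]
  v2 <- extract_all(s2)
  # correlations and ratio features of the scaled channel are unchanged
  # (ratio features divide two near-zero means, so float rounding in the
  # IIR recursion shows up at ~1e-6 relative)
  expect_equal(v2["cor.FP1_F7"], v0["cor.FP1_F7"], tolerance = 1e-8)
  expect_equal(v2["tmr.F7"], v0["tmr.F7"], tolerance = 1e-5)
  expect_equal(v2["tvr.F7"], v0["tvr.F7"], tolerance = 1e-6)
  # mean and variance scale by c and c^2
  expect_equal(unname(v2["lf_mean.F7"] / v0["lf_mean.F7"]), 2.5,
               tolerance = 1e-4)
  expect_equal(unname(v2["lf_var.F7"] / v0["lf_var.F7"]), 2.5^2,
               tolerance = 1e-5)
})

test_that("permuting channels permutes features up to pair renaming", {
  s <- random_snippet(seed = 4, n_channels = 4)
  perm <- c(2, 1, 3, 4)
  sp <- snippet(s$samples[, perm], 200)
  v <- extract_all(s)
  vp <- extract_all(sp)
  canon <- function(nm) {
    vapply(strsplit(sub("^cor\\.", "", nm), "_"), function(p)
      paste0("cor.", paste(sort(p), collapse = "_")), character(1))
  }
  vc <- v[grep("^cor\\.", names(v))]
  vpc <- vp[grep("^cor\\.", names(vp))]
  names(vc) <- canon(names(vc))
  names(vpc) <- canon(names(vpc))
  expect_equal(vc[sort(names(vc))], vpc[sort(names(vpc))], tolerance = 1e-12)
  # per-channel features travel with their channel
  for (nm in c("tmr.F7", "tvr.FP1", "lf_mean.T7", "sdiff.P7")) {
    expect_equal(vp[nm], v[nm], tolerance = 1e-12)
  }
})

test_that("feature extraction is deterministic and both routes agree", {
  s <- random_snippet(seed = 5)
  expect_identical(extract_all(s), extract_all(s))
  # assembling from cached statistics equals direct per-family computation
  st <- snippet_stats(s)
  v <- features_from_stats(st)
  base <- denoise_snippet(s)
  lf <- lowfreq_snippet(base)
  direct <- c(correlation_features(base), temporal_ratio_features(base),
              lowfreq_temporal_ratio_features(lf, prefiltered = TRUE),
              lowfreq_signal_features(lf, prefiltered = TRUE),
              sliding_difference_features(lf, prefiltered = TRUE))
  expect_identical(v, direct)
})

test_that("feature tables carry metadata and honor family subsets", {
  snips <- list(random_snippet(seed = 1), random_snippet(seed = 2))
  snips[[1]]$label <- 1L
  tbl <- featurize_snippets(snips)
  expect_equal(nrow(tbl), 2)
  expect_length(feature_columns(tbl), 127)
  expect_equal(tbl$label, c(1L, 0L))
  corr_only <- featurize_snippets(snips, families = "correlation")
  expect_length(feature_columns(corr_only), 45)
  two_ch <- featurize_snippets(snips, channels = c("Fz", "Cz"))
  expect_length(feature_columns(two_ch), choose(2, 2) + 7 * 2 + 12)  # 27
})
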