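# shared fixture builders; everything is generated in code at test time

# snippet whose channels are sinusoids (freq in Hz, amp in uV), plus optional
# white noise, at 200 Hz for 10 s
sin_snippet <- function(freqs, amps = rep(1, length(freqs)), fs = 200,
                        noise_sd = 0, seed = 1, label = 0L) {
  n <- 10 * fs
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  x <- vapply(seq_along(freqs), function(j) {
    amps[j] * sin(2 * pi * freqs[j] * t) + rnorm(n, 0, noise_sd)
  }, numeric(n))
  colnames(x) <- paste0("ch", seq_along(freqs))
  snippet(x, fs = fs, label = label)
}

# 10-channel random snippet named with the canonical montage channels
random_snippet <- function(seed = 1, fs = 200, n_channels = 10) {
  set.seed(seed)
  x <- matrix(rnorm(10 * fs * n_channels, sd = 20), ncol = n_channels)
  colnames(x) <- canonical_channels()[seq_len(n_channels)]
  snippet(x, fs = fs)
}

# 13-electrode referential recording with deterministic content
electrode_recording <- function(seed = 1, fs = 250, dur = 30,
                                pges_end_s = NULL) {
  els <- c("FP1", "F7", "T7", "P7", "O1", "FP2", "F8", "T8", "P8", "O2",
           "Fz", "Cz", "Pz")
  set.seed(seed)
  n <- dur * fs
  x <- matrix(rnorm(n * length(els), sd = 10), ncol = length(els))
  colnames(x) <- els
  recording(x, fs, els, patient_id = "PX", pges_end_s = pges_end_s)
}

# small fast dataset for harness-shape tests
small_dataset <- function(seed = 3, n_patients = 6, spp = 5) {
  cfg <- synth_config(n_patients = n_patients, duration_s = 30, seed = seed)
  suppressWarnings(generate_dataset(cfg, snippets_per_patient = spp,
                                    split = 0.7, seed = seed))
}

# brute-force Pearson correlation, independent of stats::cor
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cov <- sum((x - mx) * (y - my)) / n
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  cov / (sx * sy)
}

# brute-force sliding-difference scan over explicit window placements
sliding_brute <- function(x) {
  best <- -Inf
  s <- 0
  while (s + 50 <= length(x)) {
    w <- x[(s + 1):(s + 50)]
    best <- max(best, sum(w[26:50]) - sum(w[1:25]))
    s <- s + 10
  }
  best
}

# all-pairs Mann-Whitney AUC with half-credit ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# dominant-frequency amplitude via the discrete Fourier transform
dft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  k <- round(freq * n / fs)
  2 * Mod(fft(x)[k + 1]) / n
}
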