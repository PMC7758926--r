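# Synthetic annotated EEG: a generalized-suppression epoch (all channels
# below 10 uV) followed, after a short ramp, by higher-amplitude activity
# that is partially coherent across channels, with broadband sensor noise
# and occasional single-channel artifact transients. The generator stands in
# for protected clinical recordings; it emulates the amplitude structure the
# detector exploits, not physiological seizure waveforms.

#' Synthetic recording configuration
#'
#' @param n_patients Number of patients in a generated dataset.
#' @param fs Sampling rate in Hz (200 canonical; 250 exercises resampling).
#' @param duration_s Recording duration in seconds, or `NULL` to draw per
#'   recording from a truncated normal with mean 46.9 s and sd 33.04 s,
#'   floored at 20 s (the published duration moments of peri-ictal
#'   recordings).
#' @param suppression_amp_uv Peak amplitude during suppression; must be
#'   below the 10 uV suppression criterion (default 5).
#' @param activity_amp_uv Peak amplitude after the transition (default 40).
#' @param activity_band Character: `"slow_wave_3_8"` (3--8 Hz band noise
#'   plus a coherent 4--6 Hz oscillation), `"broadband_1_47"`, or
#'   `"mixed"` (default, the sum of both).
#' @param transition_sharpness_s Linear amplitude ramp duration at the end
#'   of suppression, seconds (default 0.5).
#' @param noise_sd_uv Standard deviation of additive white sensor noise
#'   (default 2).
#' @param drift_amp_uv Amplitude of slow (0.1--0.8 Hz) per-channel baseline
#'   wander emulating electrode drift and breathing (default 0; it sits
#'   below every analysis band, so the 1--47 Hz noise filter removes it).
#' @param artifact_rate_hz Poisson rate of short (< 0.5 s) single-channel
#'   artifact transients (default 0.05, about one or two per recording).
#' @param channel_coherence Fraction of the activity process shared across
#'   channels, in \[0, 1\] (default 0.6).
#' @param seed Master seed for the generator.
#' @return An object of class `pges_synth_config`.
#' @export
synth_config <- function(n_patients = 20L, fs = 200, duration_s = NULL,
                         suppression_amp_uv = 5, activity_amp_uv = 40,
                         activity_band = c("mixed", "slow_wave_3_8",
                                           "broadband_1_47"),
                         transition_sharpness_s = 0.5, noise_sd_uv = 2,
                         drift_amp_uv = 0, artifact_rate_hz = 0.05,
                         channel_coherence = 0.6, seed = 1L) {
  activity_band <- match.arg(activity_band)
  if (!is_number(suppression_amp_uv) || suppression_amp_uv < 0 ||
      suppression_amp_uv >= 10) {
    stop_argument("suppression_amp_uv must be in [0, 10) uV")
  }
  if (!is_number(channel_coherence) || channel_coherence < 0 ||
      channel_coherence > 1) {
    stop_argument("channel_coherence must be in [0, 1]")
  }
  if (activity_amp_uv < 0 || noise_sd_uv < 0 || artifact_rate_hz < 0 ||
      drift_amp_uv < 0) {
    stop_argument("amplitudes and rates must be non-negative")
  }
  if (!is.null(duration_s) && (!is_number(duration_s) || duration_s < 20)) {
    stop_argument("duration_s must be >= 20 s (or NULL to draw)")
  }
  structure(
    list(n_patients = as.integer(n_patients), fs = fs,
         duration_s = duration_s, suppression_amp_uv = suppression_amp_uv,
         activity_amp_uv = activity_amp_uv, activity_band = activity_band,
         transition_sharpness_s = transition_sharpness_s,
         noise_sd_uv = noise_sd_uv, drift_amp_uv = drift_amp_uv,
         artifact_rate_hz = artifact_rate_hz,
         channel_coherence = channel_coherence, seed = as.integer(seed)),
    class = "pges_synth_config")
}

# band-limited unit-scale noise: white noise pushed through the zero-phase
# bandpass, then scaled to unit max amplitude
band_noise <- function(n, band_low, band_high, fs) {
  spec <- design_bandpass(band_low, band_high, 5L, fs)
  x <- filter_zero_phase(stats::rnorm(n), spec)
  x / max(abs(x), .pges_eps)
}

activity_process <- function(n, cfg) {
  t <- (seq_len(n) - 1) / cfg$fs
  slow <- function() {
    osc <- sin(2 * pi * stats::runif(1, 4, 6) * t + stats::runif(1, 0, 2 * pi))
    0.6 * band_noise(n, 3, 8, cfg$fs) + 0.4 * osc
  }
  broad <- function() band_noise(n, 1, 47, cfg$fs)
  switch(cfg$activity_band,
         slow_wave_3_8 = slow(),
         broadband_1_47 = broad(),
         mixed = 0.6 * slow() + 0.4 * broad())
}

#' Generate one annotated synthetic recording
#'
#' The recording starts in generalized suppression (all channels under the
#' configured sub-10 uV amplitude), ramps over `transition_sharpness_s` to
#' activity at `activity_amp_uv`, and carries the transition time as its
#' end-of-PGES annotation, drawn uniformly in the middle half of the
#' recording. Deterministic given the configuration seed and patient id.
#'
#' @param cfg A [synth_config()].
#' @param patient_id Patient identifier (also seeds the per-patient draw).
#' @param electrodes If `TRUE`, emit a 13-electrode referential recording
#'   (for exercising [apply_montage()]) instead of the default 10-channel
#'   bipolar montage.
#' @return A [recording()] with `pges_end_s` set.
#' @export
generate_recording <- function(cfg, patient_id, electrodes = FALSE) {
  stopifnot(inherits(cfg, "pges_synth_config"))
  ch_names <- if (electrodes) {
    c("FP1", "F7", "T7", "P7", "O1", "FP2", "F8", "T8", "P8", "O2",
      "Fz", "Cz", "Pz")
  } else canonical_channels()
  # electrode-pair differences can double amplitudes; keep derived channels
  # inside the suppression criterion
  supp_amp <- if (electrodes) cfg$suppression_amp_uv / 2 else
    cfg$suppression_amp_uv
  act_amp <- if (electrodes) cfg$activity_amp_uv / 2 else cfg$activity_amp_uv
  with_seed(derive_seed(cfg$seed, paste0("rec_", patient_id)), {
    dur <- if (is.null(cfg$duration_s)) {
      repeat {
        d <- stats::rnorm(1, 46.90, 33.04)
        if (d >= 20) break
      }
      d
    } else cfg$duration_s
    n <- as.integer(round(dur * cfg$fs))
    pges_end <- stats::runif(1, 0.25 * dur, 0.75 * dur)
    t <- (seq_len(n) - 1) / cfg$fs
    env <- ifelse(
      t < pges_end - cfg$transition_sharpness_s, supp_amp,
      ifelse(t >= pges_end, act_amp,
             supp_amp + (act_amp - supp_amp) *
               (t - (pges_end - cfg$transition_sharpness_s)) /
               cfg$transition_sharpness_s))
    shared <- activity_process(n, cfg)
    samples <- vapply(seq_along(ch_names), function(j) {
      own <- activity_process(n, cfg)
      proc <- cfg$channel_coherence * shared +
        (1 - cfg$channel_coherence) * own
      proc <- proc / max(abs(proc), .pges_eps)
      x <- proc * env + stats::rnorm(n, 0, cfg$noise_sd_uv)
      if (cfg$drift_amp_uv > 0) {
        # baseline wander: a few sub-1-Hz components with random phases
        for (fdrift in stats::runif(3, 0.1, 0.8)) {
          x <- x + (cfg$drift_amp_uv / 3) *
            sin(2 * pi * fdrift * t + stats::runif(1, 0, 2 * pi))
        }
      }
      x
    }, numeric(n))
    # single-channel artifact transients: Gaussian-windowed 15 Hz bursts
    n_art <- stats::rpois(1, cfg$artifact_rate_hz * dur)
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        ch <- sample.int(length(ch_names), 1)
        center <- stats::runif(1, 0, dur)
        width <- stats::runif(1, 0.05, 0.2)          # burst sd; support < 0.5 s
        amp <- stats::runif(1, 30, 60)
        burst <- amp * exp(-((t - center)^2) / (2 * width^2)) *
          sin(2 * pi * 15 * (t - center))
        samples[, ch] <- samples[, ch] + burst
      }
    }
    colnames(samples) <- ch_names
    recording(samples, cfg$fs, ch_names, patient_id, pges_end)
  })
}

#' Generate a patient-disjoint labeled snippet dataset
#'
#' Generates one annotated recording per patient, cuts balanced labeled
#' snippets from each with [extract_snippets()] (the same count per patient,
#' giving near-equal class representation), and splits *patients* -- never
#' snippets -- between the training and test sides, the evaluation protocol
#' that reflects deployment on unseen patients.
#'
#' @param cfg A [synth_config()].
#' @param snippets_per_patient Snippets per class per patient (default 10).
#' @param split Fraction of patients assigned to the training side
#'   (default 0.7); both sides must receive at least one patient.
#' @param seed Master seed; overrides `cfg$seed` when given.
#' @return An object of class `pges_dataset`: lists `train` and `test` of
#'   [snippet()]s plus a `manifest` data frame recording every snippet's
#'   patient, start time, label, side and the seeds used.
#' @export
generate_dataset <- function(cfg, snippets_per_patient = 10L, split = 0.7,
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "pges_synth_config"))
  if (cfg$n_patients < 2) stop_argument("need at least 2 patients")
  n_train <- round(split * cfg$n_patients)
  if (n_train < 1 || n_train >= cfg$n_patients) {
    stop_argument("split must leave at least one patient on each side")
  }
  cfg$seed <- as.integer(seed)
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  train_ids <- with_seed(derive_seed(seed, "patient_split"),
                         sample(ids, n_train))
  per_patient <- lapply(ids, function(pid) {
    rec <- generate_recording(cfg, pid)
    if (rec$fs != 200) rec <- resample_to(rec, 200)
    snip_seed <- derive_seed(seed, paste0("snips_", pid))
    snips <- extract_snippets(rec, snippets_per_patient, snip_seed)
    got_pos <- sum(vapply(snips, function(s) s$label, integer(1)))
    if (got_pos < snippets_per_patient ||
        (length(snips) - got_pos) < snippets_per_patient) {
      warning(sprintf("patient %s: snippet shortfall (%d of %d per class)",
                      pid, min(got_pos, length(snips) - got_pos),
                      snippets_per_patient))
    }
    list(snips = snips, seed = snip_seed)
  })
  names(per_patient) <- ids
  side <- ifelse(ids %in% train_ids, "train", "test")
  manifest <- do.call(rbind, lapply(seq_along(ids), function(i) {
    snips <- per_patient[[i]]$snips
    if (length(snips) == 0) return(NULL)
    data.frame(
      patient_id = ids[i], side = side[i],
      start_s = vapply(snips, function(s) s$start_s, numeric(1)),
      label = vapply(snips, function(s) s$label, integer(1)),
      snip_seed = per_patient[[i]]$seed,
      stringsAsFactors = FALSE)
  }))
  structure(
    list(train = unlist(lapply(which(side == "train"),
                               function(i) per_patient[[i]]$snips),
                        recursive = FALSE),
         test = unlist(lapply(which(side == "test"),
                              function(i) per_patient[[i]]$snips),
                       recursive = FALSE),
         manifest = manifest, cfg = cfg, seed = as.integer(seed)),
    class = "pges_dataset")
}

#' @export
print.pges_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic snippet dataset: %d train / %d test snippets, %d patients\n",
    length(x$train), length(x$test), x$cfg$n_patients))
  invisible(x)
}

#' Write a snippet dataset to a directory
#'
#' One CSV per snippet plus a `manifest.csv` table (patient_id, side,
#' start_s, label, file) -- the serialized exchange form of a dataset.
#'
#' @param ds A `pges_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pges_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_snips <- c(ds$train, ds$test)
  sides <- c(rep("train", length(ds$train)), rep("test", length(ds$test)))
  rows <- lapply(seq_along(all_snips), function(i) {
    s <- all_snips[[i]]
    file <- sprintf("snippet_%04d.csv", i)
    dat <- as.data.frame(s$samples)
    data.table::fwrite(dat, file.path(dir, file))
    data.frame(patient_id = s$patient_id, side = sides[i],
               start_s = s$start_s, label = s$label, fs = s$fs,
               file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a snippet dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and snippet CSVs.
#' @return A `pges_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop_io(sprintf("no manifest at '%s'", mpath))
  manifest <- data.table::fread(mpath, data.table = FALSE)
  snips <- lapply(seq_len(nrow(manifest)), function(i) {
    dat <- data.table::fread(file.path(dir, manifest$file[i]),
                             data.table = FALSE)
    snippet(as.matrix(dat), fs = manifest$fs[i], label = manifest$label[i],
            patient_id = manifest$patient_id[i],
            start_s = manifest$start_s[i])
  })
  structure(
    list(train = snips[manifest$side == "train"],
         test = snips[manifest$side == "test"],
         manifest = manifest, cfg = NULL, seed = NA_integer_),
    class = "pges_dataset")
}
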