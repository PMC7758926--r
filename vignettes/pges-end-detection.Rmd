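---
title: "Detecting the end of postictal generalized EEG suppression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the end of postictal generalized EEG suppression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pges)
```

## The detection problem

Postictal generalized EEG suppression (PGES) is defined by all scalp EEG
channels falling below 10 µV after a generalized seizure. Its duration is
a candidate SUDEP risk biomarker, and the measurement bottleneck is the
*end* of the epoch: the return of activity is gradual, often slow-wave
(3–8 Hz) before normal rhythms resume, and buried in drift, movement and
muscle artifact. `pges` treats end-of-PGES detection as binary
classification of 10-s windows ("snippets") of the 10-channel longitudinal
bipolar montage (FP1–F7, F7–T7, T7–P7, P7–O1, FP2–F8, F8–T8, T8–P8, P8–O2,
Fz–Cz, Cz–Pz; each derived channel is named by its first electrode, giving
the fixed channel order FP1, F7, T7, P7, FP2, F8, T8, P8, Fz, Cz used by
every feature index). A snippet is positive exactly when the annotated
transition time lies strictly inside its window. Ten seconds corresponds
to the maximum acceptable detection latency.

The approach assumes: (i) recordings are resampled to a common 200 Hz;
(ii) the transition is a *global* event visible on most channels at once,
so inter-channel coherence rises when a window straddles it; and (iii) the
within-channel amplitude statistics of the last half of a window differ
from the first half when the transition lies between them.

## Signal conditioning

**Resampling** uses the Fourier method (truncate or zero-pad the spectrum,
with Nyquist-bin splitting/folding), which preserves in-band amplitudes to
well under 1% and leaves annotations, expressed in seconds, untouched.

**Denoising** applies a 5th-order Butterworth bandpass — "5th order" is the
prototype order, so the bandpass has 10 poles — forward and backward, so
the net phase is zero and events are not displaced in time. The effective
magnitude response is the square of the single-pass response. Edge
transients are controlled the way the standard forward–backward routines
do it: odd-extension padding of three filter lengths at each end plus
steady-state initial conditions obtained from the companion-matrix solve.
Two bands are used: 1–47 Hz (retains nearly all EEG content, −3 dB at the
edges, squared response 0.9998 at mid-band, 0.014 at 60 Hz) for general
denoising, and 3–8 Hz to isolate slow-wave activity; frequencies below
3 Hz are deliberately excluded there because drift dominates them.

Two numerical facts about zero-phase filtering of short windows are worth
stating. First, the squared response at 50 Hz is 0.27, not negligible: the
band edge at 47 Hz is close, and a 5th-order shoulder is not a brick wall.
Second, forward–backward filtering is time-reversal symmetric only away
from the window edges; the edge transients (which decay with the slowest,
1 Hz, pole) differ between a signal and its reversal in any padded
implementation, including the reference ones. Tests therefore assert the
symmetry on the interior of the window and assert the exact preservation
of a symmetric pulse's center.

## Features

Each snippet yields `C(k,2) + 7k + 12` features for k selected channels
(127 for the full montage), concatenated in the fixed order: correlations,
temporal ratios, slow-wave temporal ratios, slow-wave signal statistics,
sliding differences.

* **Correlations (45).** Pearson correlation for every unordered channel
  pair, ordered lexicographically by channel index. A zero-variance
  channel makes Pearson undefined; such pairs report 0 ("no evidence of
  linear association"), keeping the output finite.
* **Temporal ratios (24).** Per channel, mean(last half)/mean(first half)
  and var(last half)/var(first half); halves split the window exactly in
  two. Four summaries: the sum across channels of the ratio divided by the
  channel's full-window variance, and that normalized ratio for the
  least-variance channel (minimal full-window variance, ties to the lowest
  index — a proxy for the least artifact-contaminated channel), for the
  mean ratio and for the variance ratio.
* **Slow-wave temporal ratios (24).** The same statistics on the 3–8 Hz
  signal; normalizing variances are those of the filtered series itself.
* **Slow-wave statistics (22).** Mean and variance per channel of the
  3–8 Hz signal, the sum of variance-normalized means, and the normalized
  mean of the least-variance channel.
* **Sliding differences (12).** On the 3–8 Hz signal, a 50-sample (0.25 s)
  window slides in steps of 10 samples, fully contained placements only;
  each placement scores sum(last 25) − sum(first 25), and the per-channel
  feature is the maximum — a detector of upward level shifts sharper than
  the half-window ratios. Two summaries as above.

**The denominator guard.** Every ratio or normalization whose denominator
has magnitude below 1e−12 (µV or µV²) yields 0 for that feature. Zero-mean
EEG makes near-zero half-window means routine, so without a guard the
ratio features would be unbounded and classifier input could contain
infinities; 0 is a deterministic, scale-free convention. This is the
largest interpretive decision in the feature definitions: means are used
*signed*, not in absolute value, and the guard absorbs the instability
that choice creates.

Variance is population variance (divide by N). Ratios are insensitive to
the choice; the raw slow-wave variance features are not, so the convention
is fixed and stated.

For channel-subset experiments, features are *recomputed* on the subset,
never sliced from the 127-vector: pair features and all summaries (sums
across channels, least-variance channel) are subset-dependent by
definition. Internally everything reduces to a correlation matrix plus
per-channel statistics (`snippet_stats()`), computed once per snippet;
feature vectors for any subset are assembled from that cache
(`features_from_stats()`), since per-channel filtering commutes with
channel selection. The two routes are tested to agree exactly.

## Classifier and evaluation

A random forest of 501 classification trees (bootstrap sampling, `sqrt(p)`
features per split — the standard defaults; only the tree count is treated
as a chosen hyperparameter) scores a snippet by the fraction of trees
voting positive. Evaluation is always patient-independent: patients, not
snippets, are split between training and test, which is the deployment
scenario for a detector used on new patients. The ROC is built by sweeping
all distinct score thresholds; tied scores form one block traversed by a
single segment, which makes the trapezoidal area *exactly* the
Mann–Whitney statistic with half-credit ties — that equivalence is what
lets an all-pairs brute-force oracle verify the implementation to 1e−12.
Precision/recall/F1 are reported at a default threshold of 0.5 (no
operating point is privileged by the method; 0.5 is the natural vote
majority). If no snippet is predicted positive, precision is undefined and
reported as 0 with a flag.

Experiment runners (feature-family subsets, noise-filter ablation, channel
regions, channel-count sequences, exhaustive 2- and 3-channel
combinations) refit the classifier per condition, with a per-condition
seed derived deterministically from the master seed and the condition
label, so any report row can be reproduced bitwise from its stored
metadata in isolation.

## The synthetic generator

Clinical SUDEP recordings are protected, so the package generates
annotated recordings that emulate the *amplitude structure* the detector
exploits — not seizure physiology:

* a suppression epoch whose per-channel peak amplitude is
  `suppression_amp_uv` (default 5 µV, constrained below the 10 µV
  criterion), lasting until a transition time drawn uniformly from the
  middle half of the recording;
* a linear amplitude ramp of `transition_sharpness_s` (default 0.5 s) up
  to `activity_amp_uv` (default 40 µV);
* an activity process per channel mixing a shared component (weighted by
  `channel_coherence`, default 0.6) with an independent one; the band is
  slow-wave (3–8 Hz noise plus a coherent 4–6 Hz oscillation), broadband
  (1–47 Hz), or their mixture (default) — slow-wave-first because that is
  what typically follows PGES;
* additive white sensor noise (`noise_sd_uv`, default 2 µV), optional slow
  baseline wander (`drift_amp_uv`, three 0.1–0.8 Hz components, default
  0), and single-channel artifact bursts (Gaussian-windowed 15 Hz
  transients, 30–60 µV, Poisson rate `artifact_rate_hz`, default 0.05 Hz);
* durations drawn per recording from a normal with mean 46.9 s and sd
  33.04 s, truncated at 20 s — the two published moments of peri-ictal
  recording durations — unless fixed explicitly.

Two study configurations are used throughout the tests and the acceptance
script, fixed once: the **easy configuration** (all defaults: 5 µV
suppression vs 40 µV activity, 2 µV noise, 20 patients, 13 snippets per
class per patient, patient-disjoint 70/30 split), on which held-out AUC is
expected above 0.9; and the **noisy configuration** (12 µV white noise,
40 µV drift, artifact rate 0.2 Hz) for the noise-filter ablation. The
drift component is what makes that ablation meaningful: white noise alone
is half in-band, and removing its out-of-band half roughly balances the
cost of filter edge-ringing on 10-s windows, so the filter's benefit only
becomes visible — as it is in practice — when low-frequency interference
dominates. With drift present the unfiltered condition degrades into the
0.75–0.82 AUC range while the filtered one stays near 0.96, a stable
direction across seeds.

The suppression-amplitude guarantee (rolling 1-s peak below
10 µV + 3·noise sd before the transition) is stated for the suppressed
*EEG*, mirroring the clinical definition that discounts artifacts; the
invariant test therefore runs the generator with the artifact rate at 0.

What the generator does **not** emulate — and hence what green tests do
not establish about clinical data: real postictal waveform morphology,
patient-specific spectra, electrode-dependent noise, muscle/chewing
artifact structure, annotation uncertainty, and the unknown class balance
of clinical snippet sets. Synthetic results validate the machinery and the
direction of effects, not clinical performance numbers.

## Null model

The sanity null permutes labels on *both* sides of the split, breaking the
feature–label link everywhere; the resulting AUC follows the Mann–Whitney
rank null (mean 0.5, sd ≈ 0.05 at ~150 test snippets), and the tests
report the mean over five permutations for stability. Permuting only the
training labels is not a usable null at this scale: test snippets cluster
within a handful of patients, and a forest trained on chance-correlated
labels produces patient-level score structure with an AUC spread several
times wider.

## Interfaces and formats

Recordings are exchanged as EDF (16-bit, one data record, continuous
equal-rate signals; round-trip error is bounded by the quantization step
of the configured physical range) or as a plain CSV dialect (header row of
channel names, one column per channel, µV), each with a JSON sidecar
carrying the sampling rate, patient id and the end-of-PGES annotation;
bulk expert annotations also parse from two-column text
(`patient_id pges_end_seconds`). Datasets serialize as one CSV per snippet
plus a manifest. Models persist as a versioned payload with an embedded
JSON header (feature names, seed, tree count) that is checked before use.
The command-line wrapper (`inst/cli/pges.R`) exposes the pipeline with
explicit seeds, writes a JSON run-record next to every output, and exits
with distinct codes for argument (2), schema (3) and I/O (4) errors.

## Degenerate inputs and tie-breaks

* Transition exactly on a window boundary: negative (the open-interval
  rule `start < t < start + 10`); the tie must break deterministically and
  a boundary transition is not usefully "contained".
* Window starts are drawn on the sample grid; snippets may overlap (start
  times are recorded so callers can enforce non-overlap).
* Negative windows may fall anywhere that excludes the transition,
  including entirely within suppression or entirely after it.
* Recordings shorter than 10 s yield no snippets, with a warning;
  unannotated recordings yield negatives only.
* Feature extraction refuses fewer than two channels (pair features are
  undefined); prediction refuses feature tables whose column names or
  order differ from training.

## Problem sizes

The test suite runs the full study configuration (20 patients, 520
snippets) for the end-to-end checks, 6–10 patients for harness-shape
tests, and 201 trees where a forest is only a means (nulls, gradient
checks), keeping the default suite at a few minutes on one CPU; the
acceptance script uses the full 501-tree configuration throughout. These
sizes are the package's chosen study conditions and are stated here so
reruns know what the numbers refer to.

## Known limitations

* The features are amplitude- and coherence-based; rhythmic but
  low-amplitude resumption patterns would be hard for them.
* The 50 Hz mains shoulder of the 1–47 Hz band passes 27% amplitude;
  recordings from 50 Hz-mains regions may need a notch upstream.
* The time-distance evaluation metric (how far the detected end is from
  the annotation, in seconds) is out of scope; evaluation is per-snippet
  classification only.
* PGES *onset* detection is assumed given (the sub-10 µV definition);
  only the end is detected.
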