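---
title: "Within-subject pharmaco-EEG analysis: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-subject pharmaco-EEG analysis: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qeegpipe` implements a complete within-subject pharmaco-EEG analysis at
desk scale: a synthetic paired-session cohort generator, a deterministic
preprocessing chain, four quantitative EEG feature families, and
nonparametric inference by exact sign-flip cluster-based permutation tests
plus Wilcoxon signed-rank statistics with Benjamini–Hochberg correction.
This vignette is the package's own account of the science in it: what the
models are, which knobs matter, which choices were genuinely open and how
they were settled, and what passing the test suite does and does not show.

## The study design being emulated

The analysis targets a paired design: each subject is measured twice
(baseline and follow-up, e.g. before and after a course of medication),
under several EEG conditions — two resting blocks, the learning and recall
parts of a word-pair memory task, the learning part of a spatial (virtual
navigation) task, and a Simon response-conflict task — plus a battery of
behavioral measures (trial-level reaction times and accuracies, recall
counts, and paired integer score scales). Inference is entirely
nonparametric because realistic cohorts at this scale are small (8–12
pairs).

Recordings use a 29-channel 10–20 cap referenced to FCz with one
infra-orbital EOG channel, digitized at 2500 Hz. Two mastoid-adjacent
electrodes (TP9, TP10) are considered unusable due to muscle contamination
and are dropped from every analysis, leaving the 1 × 27 feature vectors
(or 40 × 27 matrices for spectra) that the statistics consume.

## The synthetic cohort

The generator is first-class, tested code, not a fixture: it defines the
study conditions under which every downstream claim is verified.

Each channel is the sum of

* **1/f background noise** — Gaussian noise synthesized in the frequency
  domain with amplitude ∝ f^(−slope/2), slope 1 by default, scaled to an
  RMS of 10 µV;
* **an alpha rhythm** — a narrowband (σ = 0.6 Hz) component centered at
  10 Hz, RMS 20 µV on the most posterior channels, attenuated toward the
  front by a weight `0.2 + 0.8 · max(0, −y)` on the template's
  anterior–posterior coordinate;
* **injected artifacts** with exact ground truth: 400-ms raised-cosine
  blink transients (250 µV peak, frontally weighted, mirrored on the EOG
  channel), 500-ms broadband muscle bursts (20–90 Hz, 90 µV RMS, temporal
  channels), 300-ms 300-µV step transients, and 2-s flat (sample-hold)
  segments, laid out on a jittered grid so events never overlap.

Subject-level variation is a stable multiplicative gain on alpha
(log-normal, σ = 0.15) and noise (σ = 0.10) shared by both sessions of a
pair; a small session-level gain jitter (σ = 0.05) creates within-pair
variability. Seeds split deterministically: each subject owns a disjoint
seed block, so enlarging a cohort never perturbs the subjects already in
it.

**Effect injection is generative, never numerical.** A follow-up "treatment
effect" is expressed as a manipulation of the waveform, so the feature
code is exercised honestly:

* *power*: the requested band's spectral amplitude is scaled by √(1 ± m);
* *Hjorth activity*: whole-channel gain √(1 ± m);
* *Hjorth mobility / brain-rate*: spectral mass is shifted between the
  low (0.5–5 Hz) and high (13–45 Hz) bands;
* *Hjorth complexity*: both spectral tails are raised (or lowered) around
  a damped alpha, widening (narrowing) the occupied bandwidth;
* *entropy decrease*: a piecewise-constant burst envelope (0.25-s
  segments, 25% duty, gain 1 + 6m) turns the amplitude distribution into a
  leptokurtic scale mixture — the per-epoch range stretches while most
  samples stay in the central bins, which lowers binned entropy; an
  entropy *increase* is produced by flattening the spectrum (more
  broadband noise, less rhythm).

The magnitude used in the effect-recovery checks (0.12 for the
central-frontal entropy decrease) was chosen with a power oracle: the
smallest magnitude at which the full pipeline recovers a negative entropy
cluster at p < 0.05 in essentially all of a batch of seeded runs at
n = 8. It is fixed once here and not tuned per run.

**Behavioral generators.** Simon sessions have exact per-block
congruent/incongruent counts (60/40 in blocks of 100, 400 trials),
randomized within block. Reaction times are shifted lognormal — shift
200 ms, meanlog log(262), sdlog 0.3, giving a congruent median near
462 ms — with the congruency effect added as a constant (48 ms by
default), so the incongruent-minus-congruent median difference equals the
configured effect in expectation. Only medians of such tasks are typically
published; any right-skewed family with a location effect would do, and
this one was chosen for having interpretable parameters. Recall counts are
binomial (60 word-pair items at mean recall probability 0.36; 50
virtual-town details at 0.62) with logit-normal subject effects shared
across sessions. Score scales are rounded, clipped Gaussians with stable
subject latents.

**What the generator does not emulate**: real scalp topographies beyond a
smooth posterior alpha gradient, non-stationarity within a session,
volume-conduction correlation structure between channels (channels are
independent apart from the common-average reference and the blink
forward model), realistic artifact morphology beyond the four stereotypes,
task-locked (event-related) dynamics, and any dependence between EEG and
behavior. Passing tests therefore demonstrates that the *pipeline* is
correct and calibrated under a plausible signal model — not that it would
detect any particular physiological effect in real data.

## Preprocessing

The chain runs in a fixed, logged order: band-pass + notch filter →
downsample to 256 Hz → ocular correction → artifact detection →
bad-channel repair → interval interpolation/exclusion → electrode
exclusion (TP9/TP10) → common-average 1-s epoching.

* **Filtering.** 4th-order Butterworth band-pass 0.5–100 Hz applied
  forward–backward: zero phase, 48 dB/oct combined asymptotic roll-off.
  The implementation computes the Butterworth and notch designs with
  `signal::butter` and the RBJ biquad formulas, then applies the
  forward–backward response |H(f)|² spectrally on mirror-padded data (3-s
  pads): this is the same zero-phase transfer function, one matrix FFT
  for all channels. The notch is a second-order IIR at 50 Hz with quality
  factor 35.
* **Downsampling** to 256 Hz: zero-phase 8th-order Butterworth anti-alias
  low-pass at 0.4 × the target rate, then cubic-spline evaluation on the
  target grid. Duration is preserved within one sample.
* **Ocular correction** is deterministic least-squares regression of each
  scalp channel on the EOG channel. Component-based (ICA) blink removal
  with visual review is not reproducible in an automated, seeded pipeline;
  regression removes ≥ 90% of a known admixture in the tests and perturbs
  EOG-uncorrelated data by < 5% RMS. This is a documented deviation from
  semiautomatic component review, adopted for determinism.
* **Artifact detection** applies three per-channel criteria at one-sample
  stride: gradient > 50 µV/ms between consecutive samples; peak-to-peak
  range > 200 µV within any 200-ms window; peak-to-peak range < 0.5 µV
  within any 100-ms window (flatline, interpreted as max − min to match
  the difference semantics of the other two criteria). Flags are dilated
  by a guard margin — ±100 ms for the transient criteria. The flatline
  guard is ±1 s: the 0.5-Hz zero-phase high-pass (time constant ≈ 0.3 s)
  smears residual ripple roughly a second into a genuinely dead segment,
  so the detectable flat interior underestimates the dead stretch by
  about that much per side. Stride, merge rules and margins are package
  decisions; the criteria themselves are fixed.
* **Repair and exclusion.** Broken channels are replaced by the unweighted
  mean of their clean neighbors over the whole recording. Detected
  intervals touching ≤ 2 channels are repaired in place the same way,
  restricted to the interval; anything wider is excluded. Neighbors come
  from a Delaunay triangulation of the template positions (2-D azimuthal
  projection) with the two implausibly long rim edges pruned, shipped as
  an explicit edge list in `inst/extdata/`.
* **Epoching.** Excluded intervals are cut; every remaining contiguous
  segment is tiled with non-overlapping 1-s epochs anchored at the
  segment's first sample (half-open intervals; remainders < 1 s
  discarded); the common average over the 27 retained channels is
  subtracted per sample within each epoch. Re-referencing within epochs
  is equivalent to re-referencing before segmentation for a common
  average on a fixed channel set.

## Features

All features are computed per 1-s, 256-sample epoch and channel, then
averaged arithmetically over epochs (per frequency bin for power). The
Simon condition is split into congruent and incongruent epochs before
averaging.

* **Hjorth parameters.** Activity = variance (µV²). Mobility =
  √(var(x′)/var(x)) with the derivative realized as the first difference
  × fs — in rad/s units, so a pure sinusoid well below Nyquist gives
  mobility ≈ its angular frequency. Complexity = mobility(x′)/mobility(x),
  equal to 1 for an ideal sine. Only ratios enter mobility and
  complexity, so the derivative scaling convention cancels where it
  matters.
* **Brain-rate** (spectrum-weighted mean frequency): fb = Σ fᵢ·pᵢ / Σ pᵢ
  over five bands with fixed centers 2, 4, 6, 10, 18 Hz, pᵢ the mean
  power in band i. The band *edges* are not fixed by the center
  convention; this package uses delta [0.5, 3), theta [3, 5), low-alpha
  [5, 7.5), alpha/low-beta [7.5, 13), beta [13, 30), exposed via
  `brainrate_bands()`. Bounded by construction to [2, 18] Hz and
  invariant to global spectrum scaling.
* **Binned Shannon entropy**: amplitudes binned into 15 equal-width bins
  spanning the epoch's own [min, max]; H = −Σ p log₂ p ≤ log₂ 15 ≈ 3.907
  bits. The count 15 is the fixed default, standing in for the grand
  average of per-epoch Freedman–Diaconis estimates over a cohort;
  `fd_bin_count()` (width 2·IQR·n^(−1/3), type-7 quantiles — bin counts
  are sensitive to the IQR convention, hence it is pinned) recomputes
  such a cohort average, and `analysis/03_features.R` prints one. The
  per-epoch binning *range* and the global *count* are deliberately
  decoupled: the count is fixed for comparability, the range adapts.
* **Power spectra**: demean, Hanning taper, FFT; a 1-s epoch at 256 Hz
  gives an exact 1-Hz grid. The analysis band is 1–40 Hz inclusive —
  exactly 40 bins, matching the 40 × 27 matrices the statistics expect.
  A nominal 0.5–45 Hz band conflicts with a 40-bin matrix at 1-Hz
  resolution; this package resolves the conflict in favor of the matrix
  shape and keeps `band = c(0.5, 45)` available behind the argument.
  Spectra are normalized per epoch (mean power over the analysis band =
  1) before averaging, consistent with all features being defined at the
  epoch level.

## Statistics

* **Cluster-based permutation tests.** Per node (electrode, or electrode ×
  frequency bin for power), the dependent-samples t statistic of the
  follow-up-minus-baseline differences; two-sided thresholding at the
  t critical value for `cluster_alpha` = 0.05 (df = n − 1; the
  cluster-forming threshold is unstated in common descriptions and this
  is the usual toolbox default); suprathreshold nodes grouped into
  connected components per polarity under the neighbor graph (spectral
  clustering adds ±1-bin frequency adjacency on the same electrode);
  cluster statistic = mass (sum of member t values). The null
  distribution of the maximal |mass| is built from *all* 2ⁿ sign-flip
  assignments of the subject differences — 256 permutations at n = 8,
  1024 at n = 10 — whenever n ≤ `max_exact_n` (default 14); beyond that a
  seeded Monte-Carlo scheme with the observed assignment included is
  available but must be enabled explicitly. Each cluster's p is the
  proportion of permutation maxima ≥ its |mass|, observed assignment
  included, so p ≥ 1/2ⁿ and the test is exact. No additional correction
  is applied across features or conditions: cluster correction is the
  correction within each test, and the families are reported side by
  side.
* **Wilcoxon signed-rank**: W = sum of positive signed ranks, average
  ranks for ties, zero differences dropped. Exact two-sided p by full
  enumeration (convolution over the rank polynomial) for n ≤ 15 without
  ties, otherwise the normal approximation with tie correction; z is
  always reported from the normal approximation. Effect size
  r = z/√(2·n_pairs) — both measurement occasions count as observations.
  With n = 12 pairs this convention reproduces published r values such as
  z = 3.06 → r ≈ 0.62; note that some reports apply the same √24 scaling
  even to n = 8 rows, where the convention is ambiguous — this package
  always uses 2·n_pairs and says so.
* **Benjamini–Hochberg** step-up adjustment is applied to the behavioral
  table as a single family (`stats::p.adjust`); EEG cluster p values are
  not BH-corrected.

## Numerical choices and degenerate inputs

Constant epochs raise a degenerate-signal error for mobility/complexity
and yield entropy 0; all-zero epochs are rejected by the spectrum
normalization; zero-variance nodes get t = 0 with a warning; all-zero
differences give p = 1, z = 0 with a warning; a recording with no
surviving full epoch yields an empty epoch set with a warning rather than
an error. Epoch tiling uses half-open [start, start + 256) intervals
anchored at segment starts. Permutation p values use the ≥-with-tolerance
comparison (10⁻¹² guard) so exact ties between the observed mass and its
mirrored permutation count correctly.

## Problem sizes

The shipped configuration runs the full study at desk scale: 8 subjects,
six conditions, 10-s recordings generated directly at 256 Hz (the
preprocessing contract is rate-agnostic, and the chain is tested
separately at 2500 Hz). Calibration uses 200 null cohorts (4-s
recordings) for the false-positive rate and 25 seeded cohorts for effect
recovery; these sizes give a 95% binomial interval of about ±0.03 around
the nominal 0.05 and a sharp pass/fail at the 80% recovery target while
keeping a full calibration run in the minutes range on one core.

## Known limitations

The generator's independence across channels understates the spatial
correlation of real EEG, which makes the cluster test's null calibration
here a necessary but not sufficient check for real recordings. Ocular
regression removes whatever is EOG-correlated, including genuine frontal
signal, and corrects blink propagation only linearly. The EDF writer
quantizes to 16 bits over each channel's observed range. The BrainVision
reader supports the multiplexed binary layouts (16-bit integer and IEEE
float) and plain bad-interval markers only. None of the simulated
distributions are estimates of any real patient population; they are
stand-ins with the statistical structure the analysis assumes.
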