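---
title: "Detecting depression from read speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting depression from read speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Speech carries reliable markers of major depressive disorder (MDD):
depressed speakers tend toward flatter prosody, reduced pitch movement and
a more monotonous spectral trajectory than healthy controls (HC). When the
speech is *text-dependent* — every participant reads the same vowel, digit
and passage scripts into a smartphone — linguistic variability is removed
by design and what remains is almost purely acoustic, which makes compact
classifiers viable.

`depspeech` implements a complete screening pipeline around that idea:

1. **Cleaning.** Spectral-gating noise reduction profiled on the leading
   0.5 s of each recording, followed by an energy-based voice activity
   detector (VAD) that removes silences.
2. **Spectral representation.** 64-band log-Mel spectrograms
   (`n_fft = 1024`, hop 512 — about 23 ms frames at 50% overlap at
   44.1 kHz), cut into fixed 64x200 patches (about 2.3 s of speech) that a
   small convolutional network consumes.
3. **Augmentation.** SpecAugment-style masking: each training patch is
   emitted raw plus time-masked, frequency-masked and doubly masked, a 4x
   expansion with labels preserved.
4. **Models.** A four-block CNN (3x3 kernels; 16, 32, 64, 32 channels;
   ReLU; 2x2 max-pooling; dense 128 and 64 with dropout 0.5; one sigmoid
   output) trained with Adam at learning rate 1e-3, batch 32, and early
   stopping on validation accuracy; plus four classical baselines on
   24-dimensional MFCC statistics — linear SVM (C = 1), LDA, kNN (k = 5,
   Euclidean) and a 100-tree Gini random forest.
5. **Evaluation.** Participant-independent stratified splits in an
   80/10/10 ratio (a 318-participant cohort yields exactly 254/32/32),
   repeated as 10 independently seeded folds; accuracy, precision, recall,
   F1 = 2PR/(P+R), ROC and trapezoid AUC at both segment and participant
   level, with the participant level (mean of segment probabilities,
   threshold 0.5) as the headline.

Because no clinical recordings ship with the package, a seeded
source-filter synthesizer (`generate_cohort()`) stands in for the study
cohort; every stage of the pipeline is exercised and tested against it.

## The synthetic cohort: what it emulates

Each utterance is built as a harmonic source filtered by resonators:

* a fundamental `f0` of 140 Hz that wanders as a mean-reverting random
  walk (10 ms steps), harmonics up to 4 kHz with 1/k amplitudes;
* three formant-like resonators near 600, 1200 and 2600 Hz (per-speaker
  jitter of about 6%) whose centres drift as independent mean-reverting
  walks, bandwidths 90/120/200 Hz;
* syllabic-rate (2.5–4.5 Hz) amplitude modulation, depth 0.12;
* breath/phrase pauses of 0.3–0.7 s at 3.5 per 10 s — read speech is
  roughly 15–20% silence, and the VAD's percentile floor estimate needs
  genuine quiet frames to lock onto;
* a 0.6 s noise-only head (deliberately longer than the 0.5 s noise
  profile the gate uses, so the profile never touches speech) and a
  stationary −60 dBFS broadband floor, a plausible quiet-room smartphone
  level;
* peak normalization to 0.9.

The **class contrast** mirrors the finding that controls show markedly
more spectral variability during utterance while depressed speech is
monotonous: the HC class gets larger pitch- and formant-wander step SDs
(1.6 vs 0.4 Hz and 8 vs 2 Hz at `variability_gap = 1`). The
`variability_gap` scalar interpolates the HC parameters between the MDD
values (gap 0, classes generatively identical) and beyond (gap 2, a strong
contrast); the group difference in MFCC3 variability is strictly
increasing in the gap. Task durations default to vowel 14 s, digit 15 s
and passage 80 s, bracketing the durations typical of clinical
reading-task recordings of these kinds.

What the generator does **not** emulate: linguistic content of any kind,
microphone coloration, room reverberation, non-stationary noise, and
between-speaker differences beyond f0/formant jitter. Passing tests on
this cohort therefore demonstrate that the pipeline recovers a planted
prosodic-variability contrast end to end — not that it detects clinical
depression; the headline accuracies reported on real cohorts are out of
reach of any synthetic stand-in.

## Numerical choices

* **Mel scale**: the 2595·log10(1 + f/700) form; triangular filters with
  centres equally spaced in mel between 0 Hz and Nyquist. A filter row
  whose triangle captures no FFT bin raises an error.
* **Log-Mel reference**: dB relative to the segment maximum, floored at
  −80 dB; masked (SpecAugment) cells are filled with the floor value.
* **STFT**: periodic Hann, no centre padding, so the frame count obeys
  `1 + floor((n - n_fft)/hop)` exactly; the 64x200 patch corresponds to
  199·512 + 1024 = 102,912 samples.
* **MFCC**: 25 ms Hamming frames at 50% overlap, FFT at the next power of
  two, 26 filters, natural log with a 1e-10 floor, orthonormal DCT-II,
  coefficients 1–12 (c0 excluded; amplitude scaling therefore leaves the
  kept coefficients unchanged). No liftering. "MFCC3" is the third kept
  coefficient.
* **Noise gate**: threshold mean + 1.5 SD of the per-frequency noise dB;
  binary mask smoothed by a 3 (frequency) x 5 (time) moving average;
  reflection padding plus window-sum-squares overlap-add keeps the output
  sample-exact in length.
* **VAD**: 30 ms frames, 10 ms hop; speech = frame RMS above
  min(5th percentile + 10 dB, −40 dBFS). The absolute arm keeps the
  detector usable on recordings that contain little silence, where a
  percentile floor estimate lands on speech itself. Gaps ≤ 200 ms merge,
  runs < 100 ms drop. Recordings with under 2 s of detected speech are
  flagged low quality and excluded — the exclusion criterion is our
  operationalization and a configuration knob, not a fixed constant.
* **Pooling stride**: a description like "2x2 max-pooling with a 1x2
  stride" admits two readings; the default halves both axes
  (stride 2,2), which yields 4x12 final maps and a compact 246,817
  parameters, in keeping with a deliberately small network. The literal
  (1,2) stride is selectable (`stride_mode = "literal_1x2"`) and grows the
  dense head to several million parameters.
* **Loss**: binary cross-entropy (the only consistent choice for a
  sigmoid unit with binary labels). He-normal initialization; dropout
  masks, shuffling and initialization all derive from one integer seed, so
  training histories are bit-reproducible on a fixed build.
* **Splits**: train = floor(0.8 N); the remainder divides equally between
  validation and test with an odd participant going to validation;
  per-class counts by largest-remainder apportionment. Ten folds are ten
  independently seeded resamples of this 80/10/10 scheme — reconciling a
  fixed 254/32/32 split with 10-fold cross-validation, both of which the
  protocol calls for.
* **Aggregation**: nothing in the protocol fixes how segment scores
  become a participant decision; we use the arithmetic mean of
  segment probabilities with ties at 0.5 going to the positive (MDD)
  class, and report both levels.
* **MFCC summarization**: statistics are computed over the whole trimmed
  utterance (the alternative per-segment reading of the protocol is
  available via the segment machinery, but the whole-utterance form is the
  default).

## Problem sizes used by the test-suite experiments

The synthetic experiments in the package's tests and acceptance script use
sizes chosen as the smallest cohorts at which the statistical checks are
stable: 60 participants (passage task) for signal recovery with
`variability_gap = 2`, 50 participants (vowel task) for the
null-configuration sanity check, 10 folds in both. Four log-Mel segments
per recording (evenly spaced across the utterance) feed the CNN — an
80 s passage yields ~60 overlapping segments of which neighbouring ones
are largely redundant, so a spread subsample represents the utterance
while keeping the training set balanced across participants. CNN training
uses up to 8 epochs with early-stopping patience 4 (batch 32, learning
rate 1e-3): on cohorts this size the validation accuracy saturates within
a few epochs and a couple more polarize the output probabilities around
the 0.5 decision threshold. The null-cohort check trains for 2 epochs —
the quantity under test (chance-level accuracy on an uninformative cohort)
does not depend on training depth.

## Known limitations

* The energy VAD assumes a roughly stationary noise floor well below
  speech level; it is not a substitute for a model-based detector in
  noisy field recordings.
* The CNN trains on CPU in single precision; run-to-run reproducibility
  holds for a fixed build, but exact histories may differ across BLAS
  builds.
* External eGeMAPS/COMPARE feature sets are ingested from CSV
  (`load_external_features()`), not computed; pretrained-backbone
  comparisons and severity-score regression are out of scope.
* With small per-fold test sets (6 participants at N = 60), fold metrics
  are coarse; mean-over-folds values are the meaningful quantities.
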