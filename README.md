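# depspeech

Automatic screening for major depressive disorder (MDD) from
text-dependent read speech — short vowel, digit and passage reading tasks
recorded on a smartphone. The package is aimed at speech/mental-health
researchers who want a complete, reproducible reference pipeline: audio
cleaning, log-Mel segmentation, SpecAugment expansion, a compact
convolutional network trained from scratch on CPU, classical
MFCC-statistic baselines, and a participant-independent cross-validated
evaluation harness. Because clinical recordings cannot be redistributed,
`depspeech` ships a seeded source-filter cohort synthesizer that emulates
the acoustic structure the analysis relies on, so everything can be run,
tested and benchmarked out of the box.

## The method

Recordings are cleaned in two steps: spectral-gating noise reduction
(noise profile = mean + 1.5 SD of the per-frequency magnitude over the
first 0.5 s, smoothed soft mask, exact-length resynthesis) and an
energy-based voice activity detector that drops silences. Clean speech is
transformed to 64-band log-Mel spectrograms (n_fft = 1024, hop = 512 at
44.1 kHz, dB re segment max, −80 dB floor) and cut into 64×200 patches
(~2.3 s). Training patches are expanded 4× by SpecAugment: raw +
time-masked + frequency-masked + both, with mask widths drawn uniformly
from {0..20} frames and {0..8} mel bands.

The classifier is a small CNN — four blocks of 3×3 convolution (16, 32,
64, 32 channels) with ReLU and 2×2 max-pooling, then dense 128 → 64 with
dropout 0.5 and a sigmoid unit (246,817 parameters) — trained with Adam
(learning rate 1e-3, batch 32, binary cross-entropy) and early stopping on
validation accuracy. Baselines use 24-dimensional MFCC statistics (mean
and SD of coefficients 1–12 computed with 25 ms Hamming frames, 26-filter
mel bank, orthonormal DCT) fed to a linear SVM (C = 1), LDA, kNN (k = 5)
and a 100-tree random forest.

Evaluation is participant-independent: stratified 80/10/10 splits at the
speaker level (a 318-participant cohort gives exactly 254/32/32), repeated
over 10 seeded folds; accuracy, precision, recall, F1 and trapezoid AUC
are reported at segment and participant level, the latter by averaging a
speaker's segment probabilities.

## Worked example

Synthesize a small cohort with a strong class contrast in prosodic
variability (`variability_gap = 2`: control-like voices wander in pitch
and formants, MDD-like voices are monotonous), then run two baselines and
inspect the report:

```r
library(depspeech)

cc <- cohort_config(n_participants = 16,
                    tasks = list(vowel = c(10, 1)),
                    variability_gap = 2, seed = 7)
ds <- prepare_dataset(cc)
ds
#> <speech_dataset> 16 recordings (0 dropped), 86 segments, 24 features

rep <- run_experiment(ds, models = c("svm_linear", "rf"),
                      n_folds = 5, seed = 42)
rep
#> <evaluation_report>
#>   task      model       level n_folds accuracy_mean accuracy_sd auc_mean
#>  vowel svm_linear participant       5             1           0        1
#>  vowel         rf participant       5             1           0        1
```

Each fold holds out one MDD-like and one control-like speaker for testing
(12 train / 2 validation / 2 test at N = 16): with a gap this large the
MFCC-statistic baselines separate the classes perfectly in every fold —
the 24-dimensional summary directly measures the planted variability
contrast. The full CNN
path runs the same way — add `"cnn"` to `models` (minutes of CPU, not
seconds). `cmd_simulate()` writes a cohort to WAV + manifest files,
`cmd_run()` executes a whole configured experiment and writes fold
metrics, summary tables and a config snapshot, and `cmd_report()` renders
mean (SD) tables; `inst/cli/depspeech.R` wraps these as shell commands.

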