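test_that("the default filterbank has the expected geometry", {
  fb <- mel_filterbank(44100, 1024, 64)
  expect_equal(dim(fb), c(64, 513))
  expect_true(all(fb >= 0))
  expect_true(all(rowSums(fb) > 0))
})

test_that("filter peaks sit on independently recomputed mel breakpoints", {
  sr <- 16000; n_fft <- 512; n_mels <- 24
  fb <- mel_filterbank(sr, n_fft, n_mels)
  centers <- oracle_mel_inv(seq(0, oracle_mel(sr / 2),
                                length.out = n_mels + 2))[2:(n_mels + 1)]
  peak_hz <- (apply(fb, 1, which.max) - 1) * sr / n_fft
  expect_true(all(abs(peak_hz - centers) <= sr / n_fft))
})

test_that("filterbank rejects impossible configurations", {
  expect_error(mel_filterbank(16000, 512, 24, fmin = 9000), "fmin")
  expect_error(mel_filterbank(8000, 64, 64), "FFT resolution")
})

test_that("silence maps to the dB floor everywhere", {
  rec <- audio_rec(numeric(44100), 44100)
  lm <- logmel(rec)
  expect_true(all(lm == -80))
})

test_that("a default-length window yields exactly 200 frames", {
  rec <- audio_rec(rnorm(102912), 44100)
  lm <- logmel(rec)
  expect_equal(dim(lm), c(64, 200))
  expect_equal(n_frames(102912, 1024, 512), 200L)
  expect_equal(max(lm), 0)
  short <- audio_rec(rnorm(500), 44100)
  expect_error(logmel(short), "shorter")
})

test_that("frame counts follow the closed form across lengths", {
  for (n in c(1024, 1500, 4096, 44100, 102912, 102913)) {
    expect_equal(n_frames(n, 1024, 512), 1L + (n - 1024L) %/% 512L)
  }
  expect_equal(n_frames(1000, 1024, 512), 0L)
})

test_that("a 1 kHz tone peaks in the mel band nearest 1 kHz", {
  sr <- 44100
  rec <- audio_rec(sin(2 * pi * 1000 * (0:(sr - 1)) / sr), sr)
  lm <- logmel(rec)
  fb_centers <- oracle_mel_inv(seq(0, oracle_mel(sr / 2),
                                   length.out = 66))[2:65]
  band_energy <- rowMeans(lm)
  expect_equal(which.max(band_energy), which.min(abs(fb_centers - 1000)))
})

test_that("doubling the waveform raises unreferenced cells by 6.02 dB", {
  rec <- make_test_voice(duration = 1, sample_rate = 44100, seed = 4)
  cfg <- spectro_config()
  a <- logmel(rec, cfg, reference = "none")
  rec2 <- rec
  rec2$samples <- rec2$samples * 2
  b <- logmel(rec2, cfg, reference = "none")
  expect_equal(max(abs((b - a) - 20 * log10(2))), 0, tolerance = 1e-6)
})

test_that("segmentation windows and pads as specified", {
  cfg <- spectro_config()
  sp <- matrix(rnorm(64 * 300), 64)
  segs <- segment_logmel(sp, cfg)
  expect_length(segs, 2)
  expect_equal(unclass(segs[[1]]), sp[, 1:200], ignore_attr = TRUE)
  expect_equal(unclass(segs[[2]]), sp[, 101:300], ignore_attr = TRUE)
  one <- segment_logmel(sp[, 1:200], cfg)
  expect_length(one, 1)
  padded <- segment_logmel(sp[, 1:150], cfg)
  expect_length(padded, 1)
  expect_equal(unclass(padded[[1]][, 1:150]), sp[, 1:150],
               ignore_attr = TRUE)
  expect_true(all(padded[[1]][, 151:200] == cfg$floor_db))
  dropped <- segment_logmel(sp[, 1:90], cfg)
  expect_length(dropped, 0)
  for (s in segs) expect_equal(dim(s), c(64, 200))
})

test_that("segment counts match brute enumeration for all lengths", {
  cfg <- spectro_config(n_mels = 4, segment_frames = 20,
                        segment_hop_frames = 7)
  for (n in 1:200) {
    segs <- segment_logmel(matrix(0, 4, n), cfg)
    expect_length(segs, oracle_segment_count(n, 20, 7))
  }
  # closed form for the unpadded part
  for (n in c(200, 350, 999, 1000)) {
    segs <- segment_logmel(matrix(0, 4, n),
                           spectro_config(n_mels = 4, segment_frames = 200,
                                          segment_hop_frames = 100,
                                          pad_policy = "drop"))
    expect_length(segs, (n - 200) %/% 100 + 1)
  }
})

test_that("the ISTFT inverts the STFT exactly on covered samples", {
  set.seed(8)
  x <- rnorm(5000)
  pad <- 512
  xp <- c(rev(x[1:pad]), x, rev(x[(5000 - pad + 1):5000]))
  S <- depspeech:::stft(xp, 1024, 512)
  y <- depspeech:::istft(S, 1024, 512, out_length = length(xp))
  expect_equal(y[pad + seq_len(5000)], x, tolerance = 1e-10)
})
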