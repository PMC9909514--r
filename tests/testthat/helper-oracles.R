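# Independent brute-force oracles used to cross-check the package's DSP and
# model arithmetic. These are written as direct translations of the defining
# formulas (explicit loops and sums), deliberately sharing no code with the
# implementation under test.

# mel scale, recomputed from the closed form
oracle_mel <- function(f) 2595 * log10(1 + f / 700)
oracle_mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

# MFCC by explicit framing, DFT, triangle filters and DCT sums
oracle_mfcc <- function(samples, sample_rate, frame_ms = 25, overlap = 0.5,
                        n_filters = 26, coeffs = 1:12, log_floor = 1e-10) {
  fl <- round(frame_ms / 1000 * sample_rate)
  hp <- round(fl * (1 - overlap))
  nf <- 1 + (length(samples) - fl) %/% hp
  n_fft <- 2^ceiling(log2(fl))
  nb <- n_fft / 2 + 1
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(fl - 1)) / (fl - 1))
  # triangle filters from mel breakpoints
  pts <- oracle_mel_inv(seq(0, oracle_mel(sample_rate / 2),
                            length.out = n_filters + 2))
  bin_hz <- (0:(nb - 1)) * sample_rate / n_fft
  out <- matrix(0, nf, length(coeffs))
  for (f in seq_len(nf)) {
    fr <- samples[(f - 1) * hp + seq_len(fl)] * ham
    spec <- fft(c(fr, rep(0, n_fft - fl)))[seq_len(nb)]
    pow <- Mod(spec)^2
    fe <- numeric(n_filters)
    for (m in seq_len(n_filters)) {
      w <- pmax(0, pmin((bin_hz - pts[m]) / (pts[m + 1] - pts[m]),
                        (pts[m + 2] - bin_hz) / (pts[m + 2] - pts[m + 1])))
      fe[m] <- sum(w * pow)
    }
    le <- log(pmax(fe, log_floor))
    for (ci in seq_along(coeffs)) {
      k <- coeffs[ci]
      s <- 0
      for (m in seq_len(n_filters))
        s <- s + le[m] * cos(pi * k * (2 * m - 1) / (2 * n_filters))
      out[f, ci] <- sqrt(2 / n_filters) * s
    }
  }
  out
}

# AUC as the Mann-Whitney U statistic over all positive/negative pairs
oracle_auc <- function(y_true, y_score) {
  pos <- y_score[y_true == 1]
  neg <- y_score[y_true == 0]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# CNN parameter count by layer arithmetic
oracle_cnn_params <- function(input_mels = 64, input_frames = 200,
                              channels = c(16, 32, 64, 32), kernel = 3,
                              pool_stride = c(2, 2), dense = c(128, 64)) {
  total <- 0
  cin <- 1
  h <- input_mels; w <- input_frames
  for (co in channels) {
    total <- total + kernel * kernel * cin * co + co
    h <- (h - 2) %/% pool_stride[1] + 1
    w <- (w - 2) %/% pool_stride[2] + 1
    cin <- co
  }
  prev <- cin * h * w
  for (d in dense) {
    total <- total + prev * d + d
    prev <- d
  }
  total + prev + 1
}

# autocorrelation pitch estimate over a voiced span
oracle_pitch <- function(x, sample_rate, fmin = 60, fmax = 400) {
  lags <- floor(sample_rate / fmax):ceiling(sample_rate / fmin)
  ac <- vapply(lags, function(L) {
    a <- x[seq_len(length(x) - L)]
    b <- x[L + seq_len(length(x) - L)]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  sample_rate / lags[which.max(ac)]
}

# brute enumeration of sliding segment windows with the half-pad rule
oracle_segment_count <- function(n, L, hop) {
  full <- if (n >= L) length(seq(0, n - L, by = hop)) else 0
  last_end <- if (full > 0) (full - 1) * hop + L else 0
  rem <- n - last_end
  full + as.integer(rem >= L / 2)
}

# short synthetic voiced recording for DSP tests (cheap, deterministic)
make_test_voice <- function(duration = 1, sample_rate = 8000, f0 = 120,
                            seed = 1) {
  set.seed(seed)
  t <- (0:(duration * sample_rate - 1)) / sample_rate
  x <- 0.5 * sin(2 * pi * f0 * t) + 0.25 * sin(2 * pi * 2 * f0 * t) +
    0.15 * sin(2 * pi * 3.3 * f0 * t) + rnorm(length(t), 0, 0.01)
  audio_rec(x / max(abs(x)) * 0.8, sample_rate)
}

# segments with disjoint band-energy signatures, separable by construction
make_separable_segments <- function(n_per_class, seed = 1, floor_db = -80) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(2 * n_per_class)) {
    lab <- as.numeric(i <= n_per_class)
    m <- matrix(floor_db + abs(rnorm(64 * 200, 0, 2)), 64, 200)
    rows <- if (lab == 1) 5:24 else 40:59
    m[rows, ] <- m[rows, ] + 60
    out[[i]] <- structure(m, participant_id = sprintf("S%03d", i),
                          task = "synthetic", label = lab,
                          segment_index = 1L)
  }
  out
}
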