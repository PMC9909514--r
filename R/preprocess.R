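#' Stationary noise reduction by spectral gating
#'
#' Learns a per-frequency noise profile from the leading noise-only span of
#' the recording (mean and SD of the STFT magnitude in dB), gates
#' time-frequency cells whose level falls below `mean + n_std * SD`, smooths
#' the resulting binary mask over neighbouring frequency and time bins into
#' a soft mask, and resynthesizes by inverse STFT. Output length and sample
#' rate equal the input's exactly.
#'
#' @param recording an [audio_rec()]
#' @param noise_profile_s seconds of leading audio treated as pure noise
#' @param n_std gate threshold in noise-level standard deviations
#' @param mask_smooth_bins integer pair: smoothing extent in (frequency,
#'   time) bins
#' @param prop_decrease fraction of attenuation applied to gated cells
#'   (1 = full suppression)
#' @param n_fft,hop STFT analysis parameters
#' @return an [audio_rec()] of identical length
#' @export
reduce_noise <- function(recording, noise_profile_s = 0.5, n_std = 1.5,
                         mask_smooth_bins = c(3, 5), prop_decrease = 1,
                         n_fft = 1024, hop = 512) {
  stopifnot(inherits(recording, "audio_rec"))
  x <- recording$samples
  sr <- recording$sample_rate
  if (duration(recording) <= noise_profile_s)
    stop("recording shorter than the noise profile window")
  if (all(x == 0)) return(recording)  # zero fixed point
  n <- length(x)
  pad <- n_fft %/% 2
  # reflect-pad so every original sample is fully covered by analysis frames
  xp <- c(rev(x[seq_len(min(pad, n))]), x, rev(x[n + 1 - seq_len(min(pad, n))]))
  win <- hann_window(n_fft)
  fr <- frame_signal(xp, n_fft, hop) * win
  nf <- ncol(fr)
  # frames fully inside the (padded) noise head define the noise profile
  noise_frames <- sum((seq_len(nf) - 1) * hop + n_fft <=
                        pad + noise_profile_s * sr)
  if (noise_frames < 2)
    stop("noise profile window too short for the STFT parameters")
  # packed real FFT: two real frames per complex transform
  nfp <- nf + nf %% 2
  if (nfp > nf) fr <- cbind(fr, 0)
  Z <- fr[, seq(1, nfp, 2), drop = FALSE] +
    1i * fr[, seq(2, nfp, 2), drop = FALSE]
  FZ <- stats::mvfft(Z)
  FZrc <- Conj(FZ[c(1, n_fft:2), , drop = FALSE])
  S1 <- (FZ + FZrc) / 2
  S2 <- (FZ - FZrc) / 2i
  nb <- n_fft / 2 + 1
  pow <- matrix(0, nb, nfp)
  h1 <- S1[seq_len(nb), , drop = FALSE]
  h2 <- S2[seq_len(nb), , drop = FALSE]
  pow[, seq(1, nfp, 2)] <- Re(h1)^2 + Im(h1)^2
  pow[, seq(2, nfp, 2)] <- Re(h2)^2 + Im(h2)^2
  pow <- pow[, seq_len(nf), drop = FALSE]
  # dB statistics only on the noise-profile frames; the full matrix is
  # compared in the power domain against the per-frequency threshold
  noise_db <- 10 * log10(pmax(pow[, seq_len(noise_frames), drop = FALSE],
                              1e-24))
  thresh_db <- rowMeans(noise_db) + n_std * apply(noise_db, 1, sd)
  mask <- smooth_mask((pow > 10^(thresh_db / 10)) * 1,
                      mask_smooth_bins[1], mask_smooth_bins[2])
  gain <- mask * prop_decrease + (1 - prop_decrease)
  if (nfp > nf) gain <- cbind(gain, 1)
  gfull <- rbind(gain, gain[seq(nb - 1, 2), , drop = FALSE])
  # gains are real, so the gated spectra stay Hermitian and repack cleanly
  Zi <- S1 * gfull[, seq(1, nfp, 2), drop = FALSE] +
    1i * (S2 * gfull[, seq(2, nfp, 2), drop = FALSE])
  zr <- stats::mvfft(Zi, inverse = TRUE) / n_fft
  fr_out <- matrix(0, n_fft, nfp)
  fr_out[, seq(1, nfp, 2)] <- Re(zr)
  fr_out[, seq(2, nfp, 2)] <- Im(zr)
  y <- overlap_add(fr_out[, seq_len(nf), drop = FALSE] * win, hop,
                   length(xp), win^2)
  out <- recording
  out$samples <- y[pad + seq_len(n)]
  out
}

# 2-D moving-average smoothing of a 0/1 mask (freq x time), edge-truncated;
# stats::filter smooths every column of a matrix in one call
smooth_mask <- function(m, f_bins, t_bins) {
  run_mean <- function(mat, k) {
    s <- stats::filter(mat, rep(1 / k, k), sides = 2)
    s[is.na(s)] <- mat[is.na(s)]
    s
  }
  if (f_bins > 1) m <- run_mean(m, f_bins)
  if (t_bins > 1) m <- t(run_mean(t(m), t_bins))
  pmax(pmin(m, 1), 0)
}

#' Energy-based voice activity detection
#'
#' Frames the signal, computes per-frame RMS in dB, and marks as speech the
#' frames exceeding the 5th-percentile frame level by `rel_threshold_db`.
#' Adjacent speech runs separated by short gaps are merged; very short runs
#' are dropped.
#'
#' @param recording an [audio_rec()]
#' @param frame_ms analysis frame length (ms)
#' @param hop_ms frame hop (ms)
#' @param rel_threshold_db speech threshold above the noise-floor estimate
#' @param abs_threshold_db absolute level (dBFS) above which a frame always
#'   counts as speech; keeps the detector sane on recordings with little or
#'   no silence, where the percentile floor estimate sits at speech level
#' @param min_speech_ms minimum retained speech-run length (ms)
#' @param max_gap_ms maximum silence gap merged into surrounding speech (ms)
#' @return a `speech_intervals` object: data frame of `(start_s, end_s)`
#'   half-open spans with attribute `total_speech_s`
#' @export
detect_voice <- function(recording, frame_ms = 30, hop_ms = 10,
                         rel_threshold_db = 10, abs_threshold_db = -40,
                         min_speech_ms = 100, max_gap_ms = 200) {
  stopifnot(inherits(recording, "audio_rec"))
  x <- recording$samples
  sr <- recording$sample_rate
  if (length(x) == 0) return(speech_intervals(numeric(0), numeric(0)))
  fl <- max(1L, round(frame_ms / 1000 * sr))
  hp <- max(1L, round(hop_ms / 1000 * sr))
  nf <- n_frames(length(x), fl, hp)
  if (nf == 0) return(speech_intervals(numeric(0), numeric(0)))
  # frame RMS via cumulative sums (no framing matrix)
  cs <- c(0, cumsum(x^2))
  starts <- (seq_len(nf) - 1L) * hp
  level <- 10 * log10(pmax((cs[starts + fl + 1L] - cs[starts + 1L]) / fl,
                           1e-20))
  floor_db <- quantile(level, 0.05, names = FALSE)
  speech <- level > min(floor_db + rel_threshold_db, abs_threshold_db)
  if (!any(speech)) return(speech_intervals(numeric(0), numeric(0)))
  runs <- rle(speech)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- cbind(starts[runs$values], ends[runs$values])
  # merge runs separated by gaps <= max_gap_ms
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (r in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      gap_frames <- iv[r, 1] - last[2] - 1L
      if (gap_frames * hop_ms <= max_gap_ms) {
        merged[[length(merged)]] <- c(last[1], iv[r, 2])
      } else merged[[length(merged) + 1L]] <- iv[r, ]
    }
  }
  iv <- do.call(rbind, merged)
  # frame span -> seconds; frame i covers [(i-1)*hp, (i-1)*hp + fl)
  start_s <- (iv[, 1] - 1L) * hp / sr
  end_s <- pmin(((iv[, 2] - 1L) * hp + fl) / sr, length(x) / sr)
  keep <- (end_s - start_s) * 1000 >= min_speech_ms
  speech_intervals(start_s[keep], end_s[keep])
}

#' Construct a speech-interval set
#' @param start_s,end_s numeric vectors of half-open span boundaries
#'   (seconds)
#' @return `speech_intervals` data frame with a `total_speech_s` attribute
#' @export
speech_intervals <- function(start_s, end_s) {
  stopifnot(length(start_s) == length(end_s), all(end_s > start_s) || length(start_s) == 0)
  o <- order(start_s)
  df <- data.frame(start_s = start_s[o], end_s = end_s[o])
  structure(df, total_speech_s = sum(df$end_s - df$start_s),
            class = c("speech_intervals", "data.frame"))
}

#' Total speech time of an interval set
#' @param intervals a [speech_intervals()] object
#' @return seconds
#' @export
total_speech_s <- function(intervals) attr(intervals, "total_speech_s")

#' Concatenate the speech spans of a recording
#'
#' @param recording an [audio_rec()]
#' @param intervals a [speech_intervals()] set within the recording
#' @return an [audio_rec()] containing only the speech spans, in order; an
#'   empty interval set yields a zero-length recording with attribute
#'   `low_quality = TRUE`
#' @export
trim_to_speech <- function(recording, intervals) {
  stopifnot(inherits(recording, "audio_rec"))
  sr <- recording$sample_rate
  n <- length(recording$samples)
  if (nrow(intervals) == 0) {
    out <- recording
    out$samples <- numeric(0)
    attr(out, "low_quality") <- TRUE
    return(out)
  }
  if (max(intervals$end_s) > n / sr + 1 / sr)
    stop("intervals extend beyond the recording")
  pieces <- lapply(seq_len(nrow(intervals)), function(i) {
    a <- floor(intervals$start_s[i] * sr) + 1L
    b <- min(n, ceiling(intervals$end_s[i] * sr))
    recording$samples[a:b]
  })
  out <- recording
  out$samples <- unlist(pieces)
  out
}

#' Clean one recording: denoise, detect speech, trim
#'
#' Recordings whose detected speech totals less than `min_speech_s` are
#' flagged low quality (attribute `low_quality`) for exclusion downstream.
#'
#' @param recording an [audio_rec()]
#' @param noise_profile_s,n_std spectral-gating parameters, see
#'   [reduce_noise()]
#' @param min_speech_s exclusion threshold on total detected speech
#' @param ... further arguments passed to [detect_voice()]
#' @return a trimmed [audio_rec()]; attribute `log` carries input/output
#'   durations and the dropped flag
#' @export
preprocess_recording <- function(recording, noise_profile_s = 0.5,
                                 n_std = 1.5, min_speech_s = 2, ...) {
  den <- reduce_noise(recording, noise_profile_s, n_std)
  iv <- detect_voice(den, ...)
  out <- trim_to_speech(den, iv)
  low <- isTRUE(attr(out, "low_quality")) || total_speech_s(iv) < min_speech_s
  attr(out, "low_quality") <- low
  attr(out, "log") <- list(input_s = duration(recording),
                           speech_s = total_speech_s(iv), dropped = low)
  out
}
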