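#' @useDynLib depspeech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats mvfft quantile rnorm runif sd setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

hann_window <- function(n) {
  # periodic Hann, the standard analysis window for overlap-add STFT
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

hamming_window <- function(n) {
  # symmetric Hamming, conventional for MFCC framing
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Number of STFT frames for a signal
#'
#' Closed-form frame count for non-centered framing: `1 + floor((n - n_fft) / hop)`.
#'
#' @param n signal length in samples
#' @param n_fft frame length in samples
#' @param hop hop size in samples
#' @return integer frame count (0 if the signal is shorter than one frame)
#' @export
n_frames <- function(n, n_fft, hop) {
  if (n < n_fft) return(0L)
  as.integer(1 + (n - n_fft) %/% hop)
}

# frame a signal into an n_fft x n_frames matrix (no centering, no padding)
frame_signal <- function(x, n_fft, hop) {
  nf <- n_frames(length(x), n_fft, hop)
  if (nf == 0) stop("signal shorter than one frame (", n_fft, " samples)")
  idx <- outer(seq_len(n_fft), (seq_len(nf) - 1L) * hop, "+")
  matrix(x[idx], nrow = n_fft)
}

# complex STFT, one column per frame; rows 1..(n_fft/2 + 1) are returned
stft <- function(x, n_fft, hop, window = hann_window(n_fft)) {
  frames <- frame_signal(x, n_fft, hop) * window
  full <- stats::mvfft(frames)
  full[seq_len(n_fft / 2 + 1), , drop = FALSE]
}

# power spectra of real windowed frames, two frames packed per complex FFT;
# frames may be shorter than n_fft (zero-padded)
power_spec_frames <- function(frames, n_fft) {
  nf <- ncol(frames)
  if (nrow(frames) < n_fft)
    frames <- rbind(frames, matrix(0, n_fft - nrow(frames), nf))
  nfp <- nf + nf %% 2
  if (nfp > nf) frames <- cbind(frames, 0)
  Z <- frames[, seq(1, nfp, 2), drop = FALSE] +
    1i * frames[, seq(2, nfp, 2), drop = FALSE]
  FZ <- stats::mvfft(Z)
  FZrc <- Conj(FZ[c(1, n_fft:2), , drop = FALSE])
  nb <- n_fft / 2 + 1
  S1 <- (FZ[seq_len(nb), , drop = FALSE] + FZrc[seq_len(nb), , drop = FALSE]) / 2
  S2 <- (FZ[seq_len(nb), , drop = FALSE] - FZrc[seq_len(nb), , drop = FALSE]) / 2i
  pow <- matrix(0, nb, nfp)
  pow[, seq(1, nfp, 2)] <- Re(S1)^2 + Im(S1)^2
  pow[, seq(2, nfp, 2)] <- Re(S2)^2 + Im(S2)^2
  pow[, seq_len(nf), drop = FALSE]
}

# inverse STFT by weighted overlap-add with window-sum-squares normalization;
# reconstructs exactly `out_length` samples (framing must have used `window`)
istft <- function(S, n_fft, hop, window = hann_window(n_fft), out_length) {
  nf <- ncol(S)
  full <- matrix(0+0i, n_fft, nf)
  full[seq_len(n_fft / 2 + 1), ] <- S
  full[seq(n_fft, n_fft / 2 + 2), ] <- Conj(S[2:(n_fft / 2), , drop = FALSE])
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  overlap_add(frames * window, hop, out_length, window^2)
}

# weighted overlap-add of windowed frames with window-sum-squares
# normalization; samples never covered by a frame stay zero
overlap_add <- function(framesw, hop, out_length, w2) {
  cpp_overlap_add(framesw, as.integer(hop), as.integer(out_length), w2)
}

rms_db <- function(x) {
  r <- sqrt(mean(x^2))
  if (r <= 0) return(-Inf)
  20 * log10(r)
}

amp_from_db <- function(db) 10^(db / 20)
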