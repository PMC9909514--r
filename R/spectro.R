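#' Log-Mel spectrogram configuration
#'
#' Defaults reproduce the 64-band, 200-frame input patches used by the CNN:
#' 1024-sample frames with hop 512 (about 23 ms / 50% overlap at 44.1 kHz),
#' 64 mel bands, dB relative to the segment maximum with a -80 dB floor.
#'
#' @param n_fft STFT frame length (samples)
#' @param hop STFT hop (samples)
#' @param n_mels number of mel bands
#' @param segment_frames frames per emitted segment
#' @param segment_hop_frames hop between segments (frames)
#' @param fmin,fmax filterbank frequency range (Hz); `fmax = NULL` means
#'   Nyquist
#' @param floor_db dB floor relative to the maximum
#' @param pad_policy `"pad_if_half"` right-pads a final remainder of at
#'   least `segment_frames / 2` with the dB floor; `"drop"` discards it
#' @return a `spectro_config` list
#' @export
spectro_config <- function(n_fft = 1024, hop = 512, n_mels = 64,
                           segment_frames = 200, segment_hop_frames = 100,
                           fmin = 0, fmax = NULL, floor_db = -80,
                           pad_policy = c("pad_if_half", "drop")) {
  stopifnot(hop <= n_fft, segment_hop_frames <= segment_frames, n_mels >= 1)
  structure(list(n_fft = n_fft, hop = hop, n_mels = n_mels,
                 segment_frames = segment_frames,
                 segment_hop_frames = segment_hop_frames,
                 fmin = fmin, fmax = fmax, floor_db = floor_db,
                 pad_policy = match.arg(pad_policy)),
            class = "spectro_config")
}

#' Hz to mel and back (HTK-style scale)
#' @param f frequency in Hz
#' @return mel value
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @param m mel value
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' Filter centres are equally spaced on the mel scale between `fmin` and
#' `fmax`; each row is a triangle over FFT bins.
#'
#' @param sample_rate sampling rate (Hz)
#' @param n_fft FFT length (samples)
#' @param n_mels number of filters
#' @param fmin,fmax frequency range (Hz); `fmax = NULL` means Nyquist
#' @return `n_mels x (n_fft/2 + 1)` non-negative weight matrix
#' @export
mel_filterbank <- function(sample_rate, n_fft, n_mels, fmin = 0, fmax = NULL) {
  if (is.null(fmax)) fmax <- sample_rate / 2
  if (!(fmin < fmax && fmax <= sample_rate / 2))
    stop("invalid config: need fmin < fmax <= sample_rate / 2")
  n_bins <- n_fft / 2 + 1
  pts_mel <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  pts_hz <- mel_to_hz(pts_mel)
  fb <- matrix(0, n_mels, n_bins)
  bin_hz <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  for (m in seq_len(n_mels)) {
    lo <- pts_hz[m]; ce <- pts_hz[m + 1]; hi <- pts_hz[m + 2]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb) == 0))
    stop("invalid config: too many mel bands for the FFT resolution ",
         "(a filter captures no FFT bin)")
  fb
}

#' Log-Mel spectrogram of a recording
#'
#' Power STFT with a periodic Hann window and no centre padding, projected
#' onto the mel filterbank, then `10 * log10`, referenced to the maximum
#' cell and floored at `floor_db`.
#'
#' @param recording an [audio_rec()]
#' @param config a [spectro_config()]
#' @param reference `"max"` (default) references dB to the maximum cell and
#'   applies the floor; `"none"` returns absolute unfloored dB (useful for
#'   energy checks)
#' @return `n_mels x n_frames` matrix in dB (max = 0, floor = `floor_db`
#'   under the default referencing)
#' @export
logmel <- function(recording, config = spectro_config(),
                   reference = c("max", "none")) {
  reference <- match.arg(reference)
  stopifnot(inherits(recording, "audio_rec"))
  x <- recording$samples
  if (length(x) < config$n_fft)
    stop("recording shorter than one analysis frame")
  frames <- frame_signal(x, config$n_fft, config$hop) *
    hann_window(config$n_fft)
  pow <- power_spec_frames(frames, config$n_fft)
  fb <- mel_filterbank(recording$sample_rate, config$n_fft, config$n_mels,
                       config$fmin, config$fmax)
  mel <- fb %*% pow
  if (reference == "none") return(10 * log10(pmax(mel, 1e-300)))
  ref <- max(mel)
  if (ref <= 0) {
    db <- matrix(config$floor_db, nrow(mel), ncol(mel))
  } else {
    db <- 10 * log10(pmax(mel / ref, 10^(config$floor_db / 10)))
  }
  db
}

#' Slice a spectrogram into fixed-size segments
#'
#' Sliding windows of `segment_frames` with step `segment_hop_frames`.
#' Under the `"pad_if_half"` policy a final remainder of at least half a
#' segment is kept and right-padded with the dB floor.
#'
#' @param spectrogram `n_mels x n_frames` dB matrix (from [logmel()])
#' @param config a [spectro_config()]
#' @param participant_id,task,label provenance carried on each segment
#' @return list of `logmel_segment` matrices (`n_mels x segment_frames`)
#'   with attributes `participant_id`, `task`, `label`, `segment_index`
#' @export
segment_logmel <- function(spectrogram, config = spectro_config(),
                           participant_id = NA_character_,
                           task = NA_character_, label = NA) {
  stopifnot(nrow(spectrogram) == config$n_mels)
  L <- config$segment_frames
  hp <- config$segment_hop_frames
  n <- ncol(spectrogram)
  starts <- integer(0)
  if (n >= L) starts <- seq(0L, n - L, by = hp)
  segs <- list()
  for (s in starts) {
    segs[[length(segs) + 1L]] <-
      new_segment(spectrogram[, s + seq_len(L), drop = FALSE],
                  participant_id, task, label, length(segs) + 1L)
  }
  # remainder handling
  last_end <- if (length(starts)) starts[length(starts)] + L else 0L
  rem <- n - last_end
  if (config$pad_policy == "pad_if_half" && rem >= L / 2) {
    start <- if (length(starts)) starts[length(starts)] + hp else 0L
    chunk <- spectrogram[, (start + 1):n, drop = FALSE]
    padded <- matrix(config$floor_db, config$n_mels, L)
    padded[, seq_len(ncol(chunk))] <- chunk
    segs[[length(segs) + 1L]] <-
      new_segment(padded, participant_id, task, label, length(segs) + 1L)
  }
  segs
}

new_segment <- function(values, participant_id, task, label, index) {
  structure(values, class = c("logmel_segment", "matrix", "array"),
            participant_id = participant_id, task = task, label = label,
            segment_index = index)
}

#' @export
print.logmel_segment <- function(x, ...) {
  cat(sprintf("<logmel_segment> %dx%d %s/%s label=%s idx=%d\n",
              nrow(x), ncol(x), attr(x, "participant_id"), attr(x, "task"),
              as.character(attr(x, "label")), attr(x, "segment_index")))
  invisible(x)
}
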