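#' MFCC extraction configuration
#'
#' Conventional short-time cepstral analysis: 25 ms Hamming frames with 50%
#' overlap, a 26-filter mel bank, natural-log energies and an orthonormal
#' type-II DCT; coefficients 1..12 are kept (coefficient 0, the overall
#' log-energy, is excluded).
#'
#' @param frame_ms frame length (ms)
#' @param overlap fractional frame overlap
#' @param n_filters number of mel filters
#' @param coeffs kept coefficient indices (1-based, excluding coefficient 0)
#' @param log_floor lower bound applied to filter energies before the log
#' @return an `mfcc_config` list
#' @export
mfcc_config <- function(frame_ms = 25, overlap = 0.5, n_filters = 26,
                        coeffs = 1:12, log_floor = 1e-10) {
  stopifnot(all(coeffs >= 1), all(coeffs <= n_filters - 1))
  structure(list(frame_ms = frame_ms, overlap = overlap,
                 n_filters = n_filters, coeffs = coeffs,
                 log_floor = log_floor),
            class = "mfcc_config")
}

# orthonormal DCT-II matrix (n_out x n_in), rows k = 1..n_out (0 excluded
# when used for MFCCs via `coeffs`)
dct_matrix <- function(n_in, ks) {
  t(vapply(ks, function(k) {
    w <- if (k == 0) sqrt(1 / n_in) else sqrt(2 / n_in)
    w * cos(pi * k * (2 * seq_len(n_in) - 1) / (2 * n_in))
  }, numeric(n_in)))
}

#' Mel-frequency cepstral coefficients of a recording
#'
#' Per frame: Hamming window, power spectrum, 26 triangular mel filter
#' energies, natural log (floored), orthonormal DCT-II, keep coefficients
#' 1..12.
#'
#' @param recording an [audio_rec()]
#' @param config an [mfcc_config()]
#' @return `n_frames x length(coeffs)` coefficient matrix
#' @export
mfcc <- function(recording, config = mfcc_config()) {
  stopifnot(inherits(recording, "audio_rec"))
  sr <- recording$sample_rate
  fl <- round(config$frame_ms / 1000 * sr)
  hp <- max(1L, round(fl * (1 - config$overlap)))
  if (length(recording$samples) < fl)
    stop("recording shorter than one analysis frame")
  n_fft <- 2^ceiling(log2(fl))
  frames <- frame_signal(recording$samples, fl, hp) * hamming_window(fl)
  pow <- power_spec_frames(frames, n_fft)
  fb <- mel_filterbank(sr, n_fft, config$n_filters, 0, sr / 2)
  loge <- log(pmax(fb %*% pow, config$log_floor))
  D <- dct_matrix(config$n_filters, config$coeffs)
  t(D %*% loge)
}

#' Summarize an MFCC series into utterance-level features
#'
#' Concatenation of the per-coefficient means and standard deviations
#' (sample SD, `n - 1` denominator): a 24-dimensional vector under the
#' default 12 coefficients.
#'
#' @param mfcc_series `n_frames x n_coeffs` matrix from [mfcc()]
#' @return named numeric vector `(mean_1..k, sd_1..k)`
#' @export
summarize_mfcc <- function(mfcc_series) {
  if (nrow(mfcc_series) < 2)
    stop("need at least 2 frames to summarize")
  k <- ncol(mfcc_series)
  out <- c(colMeans(mfcc_series), apply(mfcc_series, 2, sd))
  names(out) <- c(paste0("mfcc", seq_len(k), "_mean"),
                  paste0("mfcc", seq_len(k), "_sd"))
  out
}

#' Within-utterance variability trace of one coefficient
#'
#' Centres the chosen coefficient's trajectory on its utterance mean; the
#' trace's SD summarizes how much the coefficient moves during the
#' utterance. Depressed-like speech shows visibly flatter traces than
#' control speech for the third coefficient.
#'
#' @param mfcc_series `n_frames x n_coeffs` matrix from [mfcc()]
#' @param coeff coefficient index (1-based among the kept coefficients)
#' @return list with `trace` (zero-mean vector), `summary` (SD of the
#'   trace) and `coeff_index`
#' @export
variability_trace <- function(mfcc_series, coeff = 3) {
  if (coeff < 1 || coeff > ncol(mfcc_series))
    stop("invalid config: coeff outside the kept coefficient range")
  if (nrow(mfcc_series) < 2) stop("need at least 2 frames")
  v <- mfcc_series[, coeff] - mean(mfcc_series[, coeff])
  list(trace = v, summary = sd(v), coeff_index = coeff)
}

#' Load an external per-utterance feature table
#'
#' Ingests feature sets extracted by outside tools (openSMILE-style CSV):
#' one row per participant-task, key columns plus a fixed-width block of
#' numeric features.
#'
#' @param table_path CSV path with columns `participant_id`, `task`, then
#'   numeric feature columns
#' @return data frame with key columns and a numeric feature matrix in
#'   attribute-free columns; feature width is validated
#' @export
load_external_features <- function(table_path) {
  df <- utils::read.csv(table_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("participant_id", "task")
  if (!all(need %in% names(df)))
    stop("format error: missing join keys (participant_id, task)")
  feat_cols <- setdiff(names(df), c(need, "label", "group"))
  if (length(feat_cols) == 0) stop("format error: no feature columns")
  for (cn in feat_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0)
      stop(sprintf("format error: non-numeric value in column '%s', row %d",
                   cn, bad[1]))
    if (anyNA(v))
      stop(sprintf("format error: missing value in column '%s', row %d",
                   cn, which(is.na(v))[1]))
    df[[cn]] <- v
  }
  attr(df, "feature_cols") <- feat_cols
  df
}
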