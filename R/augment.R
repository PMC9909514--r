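#' SpecAugment configuration
#'
#' Maximum mask widths for frequency and time masking of log-Mel segments.
#' Widths are drawn uniformly from `{0..F}` (frequency bands) and `{0..W}`
#' (frames); masked cells are set to `fill` (default: the segment dB floor).
#'
#' @param F max frequency-mask width in mel bands
#' @param W max time-mask width in frames
#' @param v number of mel bands in a segment
#' @param T number of time frames in a segment
#' @param fill dB value written into masked cells
#' @param seed integer seed for the mask draws
#' @return an `augment_config` list
#' @export
augment_config <- function(F = 8, W = 20, v = 64, T = 200, fill = -80,
                           seed = 1L) {
  if (F < 0 || F > v) stop("invalid config: need 0 <= F <= v")
  if (W < 0 || W > T) stop("invalid config: need 0 <= W <= T")
  structure(list(F = F, W = W, v = v, T = T, fill = fill,
                 seed = as.integer(seed)),
            class = "augment_config")
}

# draw (width, offset) as in SpecAugment: width ~ U{0..max}, offset ~
# U{0..extent-width}; uses the current RNG stream
draw_mask <- function(max_width, extent) {
  w <- sample.int(max_width + 1L, 1L) - 1L
  o <- sample.int(extent - w + 1L, 1L) - 1L
  c(width = w, offset = o)
}

#' Mask a block of consecutive mel bands
#'
#' @param segment a `logmel_segment` (or plain matrix)
#' @param F maximum mask width in bands
#' @param fill value written into masked rows
#' @return the segment with rows `[f0, f0 + f)` set to `fill`; shape,
#'   metadata and label unchanged
#' @export
freq_mask <- function(segment, F = 8, fill = -80) {
  v <- nrow(segment)
  if (F > v) stop("invalid config: F exceeds the number of mel bands")
  d <- draw_mask(F, v)
  if (d["width"] > 0)
    segment[d["offset"] + seq_len(d["width"]), ] <- fill
  segment
}

#' Mask a block of consecutive time frames
#'
#' @param segment a `logmel_segment` (or plain matrix)
#' @param W maximum mask width in frames
#' @param fill value written into masked columns
#' @return the segment with columns `[t0, t0 + t)` set to `fill`
#' @export
time_mask <- function(segment, W = 20, fill = -80) {
  T <- ncol(segment)
  if (W > T) stop("invalid config: W exceeds the number of frames")
  d <- draw_mask(W, T)
  if (d["width"] > 0)
    segment[, d["offset"] + seq_len(d["width"])] <- fill
  segment
}

#' Expand a training set 4x by SpecAugment masking
#'
#' Emits, for every input segment, the raw segment plus a time-masked, a
#' frequency-masked, and a time-and-frequency-masked copy, preserving all
#' labels and metadata.
#'
#' @param segments list of `logmel_segment` matrices of identical shape
#' @param config an [augment_config()]
#' @return list of `4 * length(segments)` segments
#' @export
specaugment_expand <- function(segments, config = augment_config()) {
  if (length(segments) == 0) return(list())
  dims <- vapply(segments, dim, integer(2))
  if (any(dims[1, ] != config$v) || any(dims[2, ] != config$T))
    stop("invalid input: segments do not all conform to (v, T)")
  with_seed(config$seed, {
    out <- vector("list", 4L * length(segments))
    k <- 0L
    for (seg in segments) {
      out[[k + 1L]] <- seg
      out[[k + 2L]] <- time_mask(seg, config$W, config$fill)
      out[[k + 3L]] <- freq_mask(seg, config$F, config$fill)
      out[[k + 4L]] <- freq_mask(time_mask(seg, config$W, config$fill),
                                 config$F, config$fill)
      k <- k + 4L
    }
    out
  })
}
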