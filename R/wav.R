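#' Write a mono waveform to a RIFF WAV file
#'
#' Supports 16-bit integer PCM and 32-bit IEEE float encodings. Samples are
#' expected in `[-1, 1]`; 16-bit output is clipped and scaled to the integer
#' range.
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`
#' @param path output file path
#' @param sample_rate sampling rate in Hz
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float)
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, path, sample_rate = 44100L, bit_depth = 16L) {
  stopifnot(bit_depth %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- bit_depth / 8L
  data_size <- n * bytes_per
  fmt_code <- if (bit_depth == 16L) 1L else 3L  # PCM vs IEEE float
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16L) {
    x <- pmax(pmin(samples, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono RIFF WAV file
#'
#' Understands the 16-bit PCM and 32-bit float encodings written by
#' [write_wav()] (and by common recorders). Multichannel files are rejected.
#'
#' @param path WAV file path
#' @return a list with `samples` (numeric, in `[-1, 1]`) and `sample_rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bit_depth <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
      if (n_chan != 1L) stop("only mono WAV files are supported")
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk in ", path)
      if (fmt_code == 1L && bit_depth == 16L) {
        x <- readBin(con, "integer", n = size / 2, size = 2,
                     signed = TRUE, endian = "little") / 32767
      } else if (fmt_code == 3L && bit_depth == 32L) {
        x <- readBin(con, "numeric", n = size / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt_code,
             ", ", bit_depth, " bit)")
      }
      return(list(samples = x, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
}
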