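#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are expected on the `[-1, 1]` full-scale range; values outside are
#' clipped with a warning. Only the canonical 44-byte RIFF/WAVE header with a
#' single `fmt ` and `data` chunk is produced, which is what every common
#' audio tool reads.
#'
#' @param samples numeric vector of samples in `[-1, 1]`.
#' @param sample_rate sampling frequency in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    ss_stop("invalid_argument", "samples must be a non-empty numeric vector")
  }
  if (any(!is.finite(samples))) {
    ss_stop("invalid_argument", "samples contain non-finite values")
  }
  if (max(abs(samples)) > 1) {
    ss_warn("clipping", "samples exceed full scale and were clipped to [-1, 1]")
    samples <- pmin(pmax(samples, -1), 1)
  }
  pcm <- as.integer(round(samples * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path path to a WAV file written by [write_wav()] or any PCM 16-bit
#'   mono encoder. Chunks other than `fmt ` and `data` are skipped.
#' @return list with `samples` (numeric, full-scale `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    ss_stop("io", sprintf("'%s' is not a RIFF/WAVE file", path))
  }
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) {
      ss_stop("io", sprintf("'%s' has no data chunk", path))
    }
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      rest <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || rest[2] != 16L) {
        ss_stop("io", "only PCM 16-bit mono WAV is supported")
      }
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2, endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
  }
}
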