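# Minimal RIFF/WAVE PCM I/O (16-bit integer, arbitrary channels/rate).
# Only the canonical fmt/data chunks are handled, which is all the pipeline
# writes and reads.

#' Read and write PCM WAV files
#'
#' `write_wav()` stores a waveform in `[-1, 1]` as a 16-bit mono (or
#' multi-channel) RIFF PCM file; `read_wav()` reads it back, returning
#' samples rescaled to `[-1, 1]`.
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, values in `[-1, 1]`.
#' @param path file path.
#' @param sample_rate sampling rate in Hz.
#' @return `read_wav()` returns a list with `samples` and `sample_rate`.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), f, 8000)
#' w <- read_wav(f)
#' w$sample_rate
#' @export
write_wav <- function(samples, path, sample_rate = 44100L) {
  if (is.matrix(samples)) {
    n_chan <- ncol(samples)
    x <- as.vector(t(samples))          # interleave channels
  } else {
    n_chan <- 1L
    x <- as.numeric(samples)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("samples must be finite")
  x <- pmax(-1, pmin(1, x))
  pcm <- as.integer(round(x * 32767))
  byte_rate <- as.integer(sample_rate * n_chan * 2L)
  data_len <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(as.integer(n_chan * 2L), con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL; n_chan <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV supported")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported")
      extra <- len - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (id == "data") {
      n <- len %/% 2L
      pcm <- readBin(con, "integer", n, size = 2, endian = "little", signed = TRUE)
      x <- pcm / 32767
      if (n_chan > 1L)
        x <- matrix(x, ncol = n_chan, byrow = TRUE)
      return(list(samples = x, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", len + len %% 2L)   # skip unknown chunk (word-aligned)
    }
  }
}
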