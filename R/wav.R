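# Minimal mono 16-bit PCM RIFF/WAVE codec. Only the canonical uncompressed
# layout is supported; anything else is rejected with a clear message.

read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    vag_stop(sprintf("'%s' is not a RIFF/WAVE file", path), class = "vag_io_error")
  }
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    vag_stop(sprintf("'%s' is not a WAVE file", path), class = "vag_io_error")
  }
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  samples <- NULL
  repeat {
    tag <- readChar(con, 4L, useBytes = TRUE)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      channels <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1L, size = 2L, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
      if (fmt != 1L) {
        vag_stop(sprintf("'%s': only uncompressed PCM WAV is supported", path))
      }
    } else if (identical(tag, "data")) {
      samples <- readBin(con, "integer", size / 2L, size = 2L,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(sample_rate) || is.null(samples)) {
    vag_stop(sprintf("'%s': malformed WAV (missing fmt or data chunk)", path),
             class = "vag_io_error")
  }
  if (channels != 1L) {
    vag_stop(sprintf("'%s': %d channels; a single channel is required", path, channels))
  }
  if (bits != 16L) {
    vag_stop(sprintf("'%s': %d-bit samples; 16-bit PCM is required", path, bits))
  }
  list(samples = samples / 32768, sample_rate = as.numeric(sample_rate))
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantised to 16-bit integers. Mainly
#' useful for exporting synthetic signals to audio tools; the package's own
#' round trips use lossless CSV.
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav_pcm16 <- function(samples, sample_rate, path) {
  q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")                 # PCM
  writeBin(1L, con, size = 2L, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")                 # block align
  writeBin(16L, con, size = 2L, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
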