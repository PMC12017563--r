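# Minimal RIFF/WAVE PCM reader and writer for mono 16-bit files, the format
# produced by autonomous passive-acoustic recorders.  Only canonical PCM is
# supported; compressed or multi-channel files are rejected explicitly.

#' Read header information from a PCM WAV file
#'
#' Parses the RIFF header and the `fmt ` and `data` chunks without loading
#' the audio payload.
#'
#' @param path Path to a WAV file.
#' @return A list with elements `sample_rate` (Hz), `n_channels`,
#'   `bits_per_sample`, `n_samples` (frames per channel) and
#'   `duration_s` (seconds).
#' @export
wav_info <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_size <- NULL
  data_offset <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format    <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      n_channels      <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      sample_rate     <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits_per_sample <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
      fmt <- list(audio_format = audio_format, n_channels = n_channels,
                  sample_rate = sample_rate, bits_per_sample = bits_per_sample)
    } else if (identical(id, "data")) {
      data_size <- size
      data_offset <- seek(con)
      break
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(fmt) || is.null(data_size)) {
    stop("malformed WAV (missing fmt/data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L) {
    stop("only uncompressed PCM WAV is supported: ", path, call. = FALSE)
  }
  bytes_per_sample <- fmt$bits_per_sample %/% 8L
  n_frames <- data_size %/% (bytes_per_sample * fmt$n_channels)
  list(
    sample_rate = fmt$sample_rate,
    n_channels = fmt$n_channels,
    bits_per_sample = fmt$bits_per_sample,
    n_samples = n_frames,
    duration_s = n_frames / fmt$sample_rate,
    data_offset = data_offset,
    data_size = data_size
  )
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path Path to the file.
#' @return A list with `samples` (numeric vector scaled to `[-1, 1)`) and
#'   `sample_rate` (Hz).  Multi-channel or non-16-bit files raise an error;
#'   single-hydrophone campaigns are mono by construction and a silent
#'   down-mix would hide a metadata problem.
#' @export
read_wav <- function(path) {
  info <- wav_info(path)
  if (info$n_channels != 1L) {
    stop("non-mono WAV (", info$n_channels, " channels): ", path, call. = FALSE)
  }
  if (info$bits_per_sample != 16L) {
    stop("only 16-bit PCM supported (got ", info$bits_per_sample, "-bit): ",
         path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, info$data_offset)
  raw <- readBin(con, "integer", n = info$n_samples, size = 2,
                 endian = "little", signed = TRUE)
  list(samples = raw / 32768, sample_rate = info$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Values outside `[-1, 1)` are clipped.  Quantization is plain rounding
#' (no dither).
#'
#' @param samples Numeric waveform in `[-1, 1)`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  q <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
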