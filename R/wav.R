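#' Read a WAV file
#'
#' Reads RIFF/WAVE PCM audio (8/16/24/32-bit integer). Multi-channel files
#' are averaged to mono; integer PCM is scaled to the [-1, 1) range. The
#' reader walks the chunk list, so extra chunks (LIST, fact, ...) are
#' tolerated.
#'
#' @param path Path to a `.wav` file.
#' @param target_rate Optional rate (Hz) to resample to after reading.
#' @return An [audio_signal()] at the native (or requested) rate.
#' @export
load_wav <- function(path, target_rate = NULL) {
  if (!file.exists(path)) {
    dv_stop("dysvoice_error_missing_file", "no such file: %s", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    dv_stop("dysvoice_error_not_pcm", "%s is not a RIFF/WAVE file", path)
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || fmt$audio_format != 1L) {
    dv_stop("dysvoice_error_not_pcm",
            "%s: unsupported encoding (only integer PCM is read)", path)
  }
  if (is.null(data_raw) || length(data_raw) == 0) {
    dv_stop("dysvoice_error_empty_audio", "%s contains no audio samples", path)
  }
  bits <- fmt$bits
  x <- switch(as.character(bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw),
                               size = 1, signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) / 2,
                   size = 2, signed = TRUE, endian = "little") / 32768,
    "24" = read_pcm24(data_raw) / (2^23),
    "32" = readBin(data_raw, "integer", length(data_raw) / 4,
                   size = 4, endian = "little") / (2^31),
    dv_stop("dysvoice_error_not_pcm", "%s: unsupported bit depth %d", path, bits))
  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  if (length(x) == 0) {
    dv_stop("dysvoice_error_empty_audio", "%s contains no audio samples", path)
  }
  sig <- audio_signal(x, fmt$sample_rate)
  if (!is.null(target_rate) && target_rate != sig$rate) {
    sig <- resample_audio(sig, target_rate)
  }
  sig
}

read_pcm24 <- function(raw) {
  n <- length(raw) / 3
  b <- matrix(as.integer(raw), nrow = 3)
  v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
  ifelse(v >= 2^23, v - 2^24, v)
}

#' Write a WAV file (PCM 16-bit mono)
#'
#' Inverse of [load_wav()] for 16-bit mono: samples read with `load_wav`
#' and written back round-trip bit-exactly.
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(signal$samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                    # PCM
  writeBin(1L, con, size = 2, endian = "little")                    # mono
  writeBin(as.integer(signal$rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                    # block align
  writeBin(16L, con, size = 2, endian = "little")                   # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
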