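test_that("PCM16 WAV writing and reading round-trips bit-exactly", {
  set.seed(1)
  x <- round(runif(4000, -32768, 32767)) / 32768
  path <- write_temp_wav(x, 8000)
  sig <- load_wav(path)
  expect_equal(sig$rate, 8000)
  expect_identical(sig$samples, x)
})

test_that("load_wav averages stereo to mono and rescales integer PCM", {
  # hand-written stereo file with identical channels
  x <- sin(2 * pi * 100 * (0:799) / 8000) * 0.5
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  inter <- as.integer(rbind(pcm, pcm))     # L R L R ...
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  data_bytes <- length(inter) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(8000L * 4L, con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  sig <- load_wav(path)
  expect_equal(sig$samples, pcm / 32768, tolerance = 1e-12)
})

test_that("load_wav resamples to a requested rate preserving duration", {
  x <- sin(2 * pi * 440 * (0:44099) / 44100)
  path <- write_temp_wav(x, 44100)
  sig <- load_wav(path, target_rate = 8000)
  expect_equal(sig$rate, 8000)
  expect_lte(abs(length(sig$samples) - 8000), 1)
  # identity case: no target keeps the native grid
  sig0 <- load_wav(path)
  expect_equal(length(sig0$samples), 44100)
})

test_that("load_wav raises distinct error classes", {
  expect_error(load_wav(tempfile()), class = "dysvoice_error_missing_file")
  bad <- tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), bad)
  expect_error(load_wav(bad), class = "dysvoice_error_not_pcm")
  empty <- tempfile(fileext = ".wav")
  write_wav(audio_signal(numeric(1), 8000), empty)
  # truncate the data chunk to zero samples
  raw <- readBin(empty, "raw", file.info(empty)$size)
  raw[41:44] <- writeBin(0L, raw(), size = 4, endian = "little")
  writeBin(raw[1:44], empty)
  expect_error(load_wav(empty), class = "dysvoice_error_empty_audio")
})

test_that("normalize scales by the peak and is idempotent and scale-free", {
  s <- audio_signal(c(-2, 1, 2), 100)
  expect_equal(normalize(s)$samples, c(-1, 0.5, 1))
  z <- audio_signal(c(0, 0, 0), 100)
  expect_equal(normalize(z)$samples, c(0, 0, 0))
  expect_equal(normalize(audio_signal(0.5, 100))$samples, 1)
  set.seed(4)
  x <- audio_signal(rnorm(64), 100)
  n1 <- normalize(x)
  expect_equal(normalize(n1)$samples, n1$samples)
  scaled <- x; scaled$samples <- scaled$samples * 7.3
  expect_equal(normalize(scaled)$samples, n1$samples)
})

test_that("segment_fixed pads, truncates, and is idempotent", {
  pol <- segment_policy(3)
  long <- audio_signal(rnorm(5 * 8000), 8000)
  expect_length(segment_fixed(long, pol)$samples, 24000)
  short <- audio_signal(rnorm(8000), 8000)
  out <- segment_fixed(short, pol)
  expect_length(out$samples, 24000)
  expect_equal(out$samples[8001:24000], rep(0, 16000))
  exact <- audio_signal(rnorm(24000), 8000)
  expect_identical(segment_fixed(exact, pol)$samples, exact$samples)
  expect_identical(segment_fixed(segment_fixed(long, pol), pol)$samples,
                   segment_fixed(long, pol)$samples)
  # center mode keeps a centered window
  ctr <- segment_policy(1, mode = "truncate-center")
  y <- audio_signal(seq_len(30000), 10000)
  expect_equal(segment_fixed(y, ctr)$samples[1], 10001)
  expect_error(segment_policy(-1), class = "dysvoice_error_bad_policy")
})
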