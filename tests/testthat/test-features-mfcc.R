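# Direct triple-summation oracle for the cepstral transform: filterbank
# energies -> log -> explicit cosine sum, evaluated with plain loops.
mfcc_oracle <- function(signal, params, n_coeffs, n_mels) {
  sp <- stft(signal, params)
  power <- Mod(sp$values)^2
  fb <- mel_filterbank(n_mels, params$fft_size, signal$rate)
  out <- matrix(0, n_coeffs, ncol(power))
  for (t in seq_len(ncol(power))) {
    e <- pmax(as.numeric(fb %*% power[, t]), 1e-10)
    for (n in 0:(n_coeffs - 1)) {
      acc <- 0
      for (m in seq_len(n_mels)) {
        acc <- acc + log(e[m]) * cos(pi * n * (m - 0.5) / n_mels)
      }
      out[n + 1, t] <- acc
    }
  }
  out
}

test_that("mfcc_stack equals the explicit summation oracle", {
  s <- clean_vowel()
  short <- audio_signal(s$samples[1:3200], s$rate)
  p <- stft_params(8000)
  got <- mfcc_stack(short, p, n_coeffs = 8, n_mels = 20)
  want <- mfcc_oracle(short, p, 8, 20)
  expect_lt(max(abs(got$mfcc - want)) / max(abs(want)), 1e-8)
})

test_that("flat filterbank energies give zero cepstra above order 0", {
  # the cosine transform of a constant log-energy vector vanishes for n >= 1
  n_mels <- 24
  m <- seq_len(n_mels)
  loge <- rep(3.7, n_mels)
  coeffs <- vapply(0:12, function(n) sum(loge * cos(pi * n * (m - 0.5) / n_mels)),
                   numeric(1))
  expect_lt(max(abs(coeffs[-1])), 1e-10)
  expect_equal(coeffs[1], 3.7 * n_mels)
})

test_that("delta features evaluate the regression formula", {
  # linear ramp c_t = a * t -> delta = a on interior frames
  a <- 0.37
  ramp <- matrix(a * (1:40), nrow = 1)
  d <- delta_features(ramp, width = 2)
  expect_equal(as.numeric(d[1, 3:38]), rep(a, 36), tolerance = 1e-12)
  # delta of a constant track is zero everywhere
  expect_true(all(delta_features(matrix(5, 1, 30), 2) == 0))
})

test_that("mel spectrograms have the fixed model-input geometry", {
  s <- clean_vowel()
  m <- mel_spectrogram(s)
  expect_equal(dim(m$values), c(128, 40))
  sil <- mel_spectrogram(audio_signal(numeric(24000), 8000))
  expect_true(all(sil$values == sil$db_floor))
  # a 1 kHz tone peaks in the mel band whose center is nearest 1 kHz
  tone <- audio_signal(sin(2 * pi * 1000 * (0:23999) / 8000), 8000)
  mt <- mel_spectrogram(tone)
  peak_band <- which.max(rowMeans(mt$values))
  expect_lt(abs(mt$mel_centers_hz[peak_band] - 1000), 80)
})

test_that("featurize yields the fixed schema, deterministically", {
  s <- synth_vowel(preset_profiles()$hc, 8000, seed = 5)
  f1 <- featurize(s)
  f2 <- featurize(s)
  expect_identical(f1, f2)
  expect_equal(names(f1), c(feature_schema(), "label"))
  expect_equal(f1$label, "HC")
  expect_true(all(is.finite(as.numeric(f1[feature_schema()]))))
  # fully unvoiced input keeps the schema with NA voice-quality fields
  set.seed(2)
  fn <- featurize(audio_signal(rnorm(8000), 8000))
  expect_equal(names(fn), c(feature_schema(), "label"))
  expect_true(is.na(fn$jitter_pct))
  expect_true(is.na(fn$hnr_db))
  expect_false(anyNA(fn[c("zcr_mean", "centroid_mean", "mfcc0_mean")]))
})
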