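test_that("stft concentrates a bin-centered tone and maps silence to zero", {
  rate <- 8000
  p <- stft_params(rate, frame_length = 256, hop = 128, fft_size = 256)
  f_bin <- 32 * rate / 256                      # exactly bin 33
  tone <- audio_signal(sin(2 * pi * f_bin * (0:4095) / rate), rate)
  sp <- stft(tone, p)
  mags <- Mod(sp$values)
  peak_bin <- apply(mags, 2, which.max)
  expect_true(all(peak_bin == 33))
  # outside the Hann mainlobe (+-2 bins) everything is far below the peak
  expect_true(all(mags[33, ] >
                    10 * apply(mags[-(31:35), , drop = FALSE], 2, max)))
  zero <- stft(audio_signal(numeric(4096), rate), p)
  expect_true(all(Mod(zero$values) == 0))
})

test_that("istft reconstructs the analyzed signal to numerical precision", {
  set.seed(11)
  x <- rnorm(4000)
  sig <- audio_signal(x, 8000)
  p <- stft_params(8000)
  rec <- istft(stft(sig, p))
  covered <- length(rec$samples)
  # interior of the covered region (the first sample sits at the window zero)
  idx <- 2:covered
  expect_lt(max(abs(rec$samples[idx] - x[idx])), 1e-6)
})

test_that("noise PSD is the mean squared magnitude of the leading frames", {
  rate <- 8000
  p <- stft_params(rate, frame_length = 64, hop = 64, fft_size = 64)
  # frames with constant magnitude: a constant signal has all energy in bin 1
  const <- audio_signal(rep(0.5, 64 * 12), rate)
  sp <- stft(const, p)
  prof <- estimate_noise_psd(sp, 10)
  expect_equal(prof$psd, rowMeans(Mod(sp$values[, 1:10])^2))
  expect_equal(prof$n_frames_used, 10L)
  # only the leading frames are used
  head_zero <- audio_signal(c(numeric(64 * 10), rnorm(64 * 5)), rate)
  expect_equal(estimate_noise_psd(stft(head_zero, p), 10)$psd,
               rep(0, 33))
  # hand evaluation: two frames with bin magnitudes 1 and 3 -> (1+9)/2 = 5
  fake <- stft(const, p)
  fake$values <- matrix(complex(modulus = rep(c(1, 3), each = 33),
                                argument = 0.2), nrow = 33)
  expect_equal(estimate_noise_psd(fake, 2)$psd, rep(5, 33))
  expect_error(estimate_noise_psd(fake, 3),
               class = "dysvoice_error_too_few_frames")
})

test_that("the spectral gate passes loud bins, scales quiet bins by alpha", {
  sp <- stft(audio_signal(rnorm(2000), 8000))
  prof <- estimate_noise_psd(sp, 10)
  # force a known threshold landscape
  prof$psd <- rep(4, length(prof$psd))          # T(f) = k * 4 = 6 (power)
  loud <- sp
  loud$values[] <- complex(modulus = 10, argument = 0.7)
  out <- spectral_gate(loud, prof, gate_params(k = 1.5, alpha = 0.1))
  expect_equal(out$values, loud$values)          # |X|^2 = 100 > 6: untouched
  quiet <- sp
  quiet$values[] <- complex(modulus = 1, argument = -0.4)
  out2 <- spectral_gate(quiet, prof, gate_params(k = 1.5, alpha = 0.1))
  expect_equal(Mod(out2$values), Mod(quiet$values) * 0.1)
  expect_equal(Arg(out2$values), Arg(quiet$values))   # phase preserved
  # alpha = 1 is the identity regardless of threshold
  out3 <- spectral_gate(quiet, prof, gate_params(k = 1.5, alpha = 1))
  expect_equal(out3$values, quiet$values)
  bad <- prof; bad$psd <- bad$psd[-1]
  expect_error(spectral_gate(quiet, bad, gate_params()),
               class = "dysvoice_error_grid_mismatch")
})

test_that("gating is a contraction, monotone in k, and energy-bounded", {
  set.seed(5)
  sig <- audio_signal(rnorm(6000), 8000)
  sp <- stft(sig)
  prof <- estimate_noise_psd(sp, 10)
  for (k in c(0.5, 1.5, 4)) {
    out <- spectral_gate(sp, prof, gate_params(k = k, alpha = 0.1))
    expect_true(all(Mod(out$values) <= Mod(sp$values) + 1e-12))
  }
  m1 <- Mod(spectral_gate(sp, prof, gate_params(k = 1))$values)
  m2 <- Mod(spectral_gate(sp, prof, gate_params(k = 2))$values)
  expect_true(all(m2 <= m1 + 1e-12))
  den <- denoise(sig)
  expect_lte(sum(den$samples^2),
             sum(normalize(sig)$samples^2) * (1 + 1e-6))
})

test_that("denoise preserves silence, clean tones, and improves SNR", {
  rate <- 8000
  expect_equal(denoise(audio_signal(numeric(8000), rate))$samples,
               numeric(8000))
  # clean tone with a silent head: preserved almost exactly
  tt <- (0:(2 * rate - 1)) / rate
  clean <- c(numeric(1200), sin(2 * pi * 500 * tt))
  den <- denoise(audio_signal(clean, rate))
  idx <- 2000:15000
  expect_gt(cor(den$samples[idx], clean[idx]), 0.99)
  # tone + white noise at ~0 dB SNR: output closer to the clean reference
  set.seed(21)
  noise <- rnorm(length(clean)) * sqrt(mean(clean^2))
  noisy <- audio_signal(clean + noise, rate)
  den2 <- denoise(noisy)
  snr <- function(est, ref) {
    a <- sum(est * ref) / sum(ref^2)
    10 * log10(sum((a * ref)^2) / sum((est - a * ref)^2))
  }
  expect_gt(snr(den2$samples[idx], clean[idx]),
            snr(normalize(noisy)$samples[idx], clean[idx]))
  expect_gt(abs(cor(den2$samples[idx], clean[idx])),
            abs(cor(noisy$samples[idx], clean[idx])))
})
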