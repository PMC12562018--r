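test_that("pitch tracking locks onto a pure tone and rejects noise/silence", {
  rate <- 8000
  tone <- audio_signal(sin(2 * pi * 200 * (0:(2 * rate - 1)) / rate), rate)
  tr <- track_f0(tone)
  expect_gt(mean(tr$voicing), 0.9)
  expect_true(all(abs(tr$f0[tr$voicing] - 200) < 2))
  set.seed(12)
  noise <- audio_signal(rnorm(2 * rate), rate)
  trn <- track_f0(noise)
  expect_lt(mean(trn$voicing), 0.5)
  sil <- track_f0(audio_signal(numeric(rate), rate))
  expect_true(all(!sil$voicing))
  expect_true(all(sil$f0 == 0))
  expect_error(track_f0(tone, range = c(500, 100)),
               class = "dysvoice_error_bad_range")
})

test_that("cycle extraction recovers exact periodicity and AM envelopes", {
  # steady synthetic vowel: all periods within a sample of 5 ms
  s <- clean_vowel()
  cy <- extract_cycles(s)
  expect_true(all(abs(cy$periods - 0.005) < 1 / 8000))
  # amplitude-modulated vowel: periods stay constant, amplitudes follow
  # the (slow) modulation envelope
  am <- s
  tt <- (seq_along(am$samples) - 1) / am$rate
  env <- 1 + 0.4 * sin(2 * pi * 1.5 * tt)
  am$samples <- am$samples * env
  cya <- extract_cycles(am)
  expect_true(all(abs(cya$periods - 0.005) < 1.5 / 8000))
  mark_env <- env[round(cya$marks[-length(cya$marks)])][cya$valid]
  expect_gt(cor(cya$amplitudes, mark_env), 0.95)
  # unvoiced input violates the precondition
  set.seed(13)
  expect_error(extract_cycles(audio_signal(rnorm(8000), 8000)),
               class = "dysvoice_error")
})

test_that("jitter evaluates the printed formula and is scale-invariant", {
  cy <- manual_cycles(c(10, 10.5, 10, 10.5) / 1000)
  expect_equal(jitter_percent(cy), 100 * 0.5 / 10.25, tolerance = 1e-12)
  expect_equal(jitter_percent(manual_cycles(rep(0.008, 20))), 0)
  cy2 <- manual_cycles(2 * c(10, 10.5, 10, 10.5) / 1000)
  expect_equal(jitter_percent(cy2), jitter_percent(cy))
  expect_error(jitter_percent(manual_cycles(0.01)),
               class = "dysvoice_error_too_few_cycles")
})

test_that("shimmer evaluates the printed formula and is scale-invariant", {
  cy <- manual_cycles(rep(0.005, 3), amplitudes = c(1.0, 0.9, 1.0))
  expect_equal(shimmer_percent(cy), 100 * 0.1 / (2.9 / 3), tolerance = 1e-12)
  expect_equal(shimmer_percent(manual_cycles(rep(0.005, 5), rep(0.7, 5))), 0)
  cy2 <- manual_cycles(rep(0.005, 3), amplitudes = 3 * c(1.0, 0.9, 1.0))
  expect_equal(shimmer_percent(cy2), shimmer_percent(cy))
  # dB companion: mean |20 log10 ratio|
  expect_equal(shimmer_db(cy),
               mean(abs(20 * log10(c(0.9 / 1, 1 / 0.9)))))
  expect_error(shimmer_percent(manual_cycles(rep(0.005, 3), c(0, 0, 0))),
               class = "dysvoice_error_degenerate")
})

test_that("jitter and shimmer are non-negative on extracted voices", {
  set.seed(3)
  for (j in c(0.5, 3)) {
    p <- voice_profile(f0_mean = 160, jitter_pct = j, hnr_db = 12)
    cy <- extract_cycles(synth_vowel(p, 8000, seed = round(j * 10)))
    expect_gte(jitter_percent(cy), 0)
    expect_gte(shimmer_percent(cy), 0)
    expect_true(all(cy$periods > 0))
    expect_true(all(cy$amplitudes >= 0))
  }
})

test_that("HNR recovers a known harmonic-to-noise mixing ratio", {
  # power ratio 20:1 -> 13.01 dB
  p <- voice_profile(f0_mean = 200, f0_sd = 5, jitter_pct = 0.3,
                     shimmer_pct = 2, hnr_db = 10 * log10(20))
  est <- hnr_db(synth_vowel(p, 8000, seed = 7))
  expect_lt(abs(est - 10 * log10(20)), 1.5)
  expect_error(hnr_db(audio_signal(numeric(8000), 8000)),
               class = "dysvoice_error")
})
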