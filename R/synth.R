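#' Voice synthesis profile
#'
#' Control parameters for the dysphonic sustained-vowel synthesizer:
#' fundamental frequency and its slow variability, cycle-to-cycle jitter and
#' shimmer targets, harmonics-to-noise ratio, vowel formants, duration and
#' an optional slow tremor modulation.
#'
#' @param f0_mean Mean fundamental frequency, Hz (75-500).
#' @param f0_sd Slow F0 variability (sd of the smooth pitch drift), Hz.
#' @param jitter_pct Target extracted jitter, percent.
#' @param shimmer_pct Target extracted shimmer, percent.
#' @param hnr_db Harmonic-to-noise power ratio in dB used for mixing.
#' @param formants Formant frequencies (F1, F2, F3) in Hz; defaults are the
#'   open vowel /a/.
#' @param formant_bw Formant bandwidths in Hz.
#' @param duration Duration in seconds.
#' @param tremor_rate Optional sinusoidal F0 tremor rate in Hz (0 = none).
#' @param label Class tag (`"PD"`, `"HC"`, `"unknown"`).
#' @return A `voice_profile` object.
#' @export
voice_profile <- function(f0_mean = 200, f0_sd = 5, jitter_pct = 0.3,
                          shimmer_pct = 2, hnr_db = 15,
                          formants = c(700, 1200, 2600),
                          formant_bw = c(90, 110, 170),
                          duration = 3, tremor_rate = 0,
                          label = "unknown") {
  if (f0_mean < 75 || f0_mean > 500) {
    dv_stop("dysvoice_error_bad_profile", "f0_mean must lie in 75-500 Hz")
  }
  vals <- c(f0_sd, jitter_pct, shimmer_pct, tremor_rate, formants, formant_bw)
  if (any(vals < 0) || duration <= 0) {
    dv_stop("dysvoice_error_bad_profile",
            "profile parameters must be non-negative and duration > 0")
  }
  structure(list(f0_mean = f0_mean, f0_sd = f0_sd, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, hnr_db = hnr_db,
                 formants = formants, formant_bw = formant_bw,
                 duration = duration, tremor_rate = tremor_rate,
                 label = match.arg(label, c("unknown", "PD", "HC"))),
            class = "voice_profile")
}

#' Preset pathological and healthy voice profiles
#'
#' The healthy preset sits inside the normal ranges (jitter <= 0.5 %,
#' HNR >= 10 dB, moderate pitch variability); the pathological preset
#' reflects hypokinetic dysarthria: jitter in the 3-5 % band, elevated
#' shimmer, HNR <= 7 dB (breathy), and reduced F0 variability (monotone).
#'
#' @return A list with elements `pd` and `hc`, both [voice_profile()]s.
#' @export
preset_profiles <- function() {
  list(
    pd = voice_profile(f0_mean = 180, f0_sd = 1.5, jitter_pct = 4,
                       shimmer_pct = 8, hnr_db = 5, label = "PD"),
    hc = voice_profile(f0_mean = 200, f0_sd = 5, jitter_pct = 0.3,
                       shimmer_pct = 2, hnr_db = 15, label = "HC")
  )
}

# Rosenberg-style glottal flow pulse on normalized phase [0, 1).
rosenberg_pulse <- function(phase, open = 0.4, close = 0.2) {
  g <- numeric(length(phase))
  rise <- !is.na(phase) & phase >= 0 & phase < open
  fall <- !is.na(phase) & phase >= open & phase < open + close
  g[rise] <- 0.5 * (1 - cos(pi * phase[rise] / open))
  g[fall] <- cos(pi * (phase[fall] - open) / (2 * close))
  g
}

# Expected mean-|successive difference| of iid N(0, s) perturbations is
# (2/sqrt(pi)) * s; the synthesizer scales requested percentages by the
# inverse so the extracted statistic matches the request.
perturbation_scale <- sqrt(pi) / 2

#' Synthesize a dysphonic sustained vowel
#'
#' Source-filter synthesis. Glottal cycle onset times are laid out in
#' continuous time with independent Gaussian per-cycle period perturbations
#' (scaled so that the extracted jitter statistic matches `jitter_pct`) on
#' top of a smooth F0 drift of sd `f0_sd`; per-cycle amplitudes are
#' perturbed analogously for shimmer. The glottal pulse is evaluated at the
#' continuous phase (no sample quantization of periods), differentiated,
#' and passed through a cascade of two-pole formant resonators. Aspiration
#' noise is filtered through the same cascade and mixed so the harmonic-to-
#' noise power ratio equals `10^(hnr_db/10)` over the phonated region.
#' Deterministic given `seed`.
#'
#' @param profile A [voice_profile()].
#' @param rate Sampling rate in Hz (default 8000, the telephone-band rate).
#' @param seed Integer RNG seed.
#' @param lowpass_hz Optional low-pass cutoff (e.g. 4000 to emulate the
#'   telephone band when synthesizing at a higher rate).
#' @return An [audio_signal()] carrying the profile's label.
#' @export
synth_vowel <- function(profile, rate = 8000, seed = 1, lowpass_hz = NULL) {
  stopifnot(inherits(profile, "voice_profile"))
  with_seed(seed, {
    dur <- profile$duration
    n <- round(dur * rate)
    tt <- (seq_len(n) - 1) / rate
    # smooth pitch drift: spline through control points every 250 ms
    n_ctrl <- max(4, ceiling(dur / 0.25) + 1)
    ctrl_t <- seq(0, dur, length.out = n_ctrl)
    ctrl_f <- profile$f0_mean + rnorm(n_ctrl, 0, profile$f0_sd)
    f0_of <- stats::splinefun(ctrl_t, ctrl_f, method = "natural")
    tremor <- function(t) {
      if (profile$tremor_rate > 0)
        0.02 * profile$f0_mean * sin(2 * pi * profile$tremor_rate * t)
      else 0
    }
    sj <- profile$jitter_pct / 100 * perturbation_scale
    ss <- profile$shimmer_pct / 100 * perturbation_scale
    onsets <- numeric(ceiling(dur * 520) + 8)
    periods <- numeric(length(onsets))
    shape_periods <- numeric(length(onsets))
    amps <- numeric(length(onsets))
    t_cur <- 0.005
    i <- 0
    while (t_cur < dur) {
      i <- i + 1
      f0 <- max(50, f0_of(t_cur) + tremor(t_cur))
      t_base <- 1 / f0
      periods[i] <- max(0.3 * t_base, t_base * (1 + sj * rnorm(1)))
      # the pulse SHAPE follows the smooth F0 contour: jitter perturbs
      # cycle timing only, so waveform landmarks stay phase-locked to onsets
      shape_periods[i] <- t_base
      amps[i] <- max(0.05, 1 + ss * rnorm(1))
      onsets[i] <- t_cur
      t_cur <- t_cur + periods[i]
    }
    onsets <- onsets[seq_len(i)]; periods <- periods[seq_len(i)]
    shape_periods <- shape_periods[seq_len(i)]
    amps <- amps[seq_len(i)]
    # band-limited source generation: the glottal flow derivative has sharp
    # corners, so it is rendered at 4x oversampling and decimated after the
    # formant filter (classic anti-aliased source-filter synthesis)
    ov <- 4L
    tt4 <- (seq_len(n * ov) - 1) / (rate * ov)
    cyc4 <- findInterval(tt4, onsets)
    inside4 <- cyc4 >= 1
    phase <- rep(NA_real_, n * ov)
    phase[inside4] <- (tt4[inside4] - onsets[cyc4[inside4]]) /
      shape_periods[cyc4[inside4]]
    flow <- rosenberg_pulse(phase)
    flow[inside4] <- flow[inside4] * amps[cyc4[inside4]]
    source <- c(0, diff(flow))                 # glottal flow derivative shape
    harm4 <- formant_cascade(source, rate * ov, profile$formants,
                             profile$formant_bw)
    harm <- as.numeric(signal::resample(harm4, 1, ov))
    harm <- c(harm, numeric(n))[seq_len(n)]
    cyc <- findInterval(tt, onsets)
    inside <- cyc >= 1
    active <- inside & tt <= onsets[i] + periods[i]
    p_harm <- mean(harm[active]^2)
    noise <- formant_cascade(rnorm(n), rate, profile$formants,
                             profile$formant_bw)
    p_noise_raw <- mean(noise[active]^2)
    scale <- sqrt(p_harm / (10^(profile$hnr_db / 10) * p_noise_raw))
    x <- harm + scale * noise
    if (!is.null(lowpass_hz) && lowpass_hz < rate / 2) {
      bf <- signal::butter(6, lowpass_hz / (rate / 2))
      x <- as.numeric(signal::filter(bf, x))
    }
    x <- apply_fade(x, rate, 0.015)
    x <- x / max(abs(x)) * 0.95
    out <- audio_signal(x, rate, profile$label)
    # synthesis ground truth, for parameter-recovery testing
    attr(out, "onsets") <- onsets
    attr(out, "periods") <- periods
    attr(out, "cycle_amps") <- amps
    out
  })
}

formant_cascade <- function(x, rate, formants, bandwidths) {
  for (j in seq_along(formants)) {
    r <- exp(-pi * bandwidths[j] / rate)
    theta <- 2 * pi * formants[j] / rate
    a <- c(1, -2 * r * cos(theta), r^2)
    x <- as.numeric(signal::filter(1 - r, a, x))
  }
  x
}

apply_fade <- function(x, rate, fade_s) {
  nf <- min(round(fade_s * rate), floor(length(x) / 2))
  if (nf > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nf) - 0.5) / nf))
    x[seq_len(nf)] <- x[seq_len(nf)] * ramp
    x[(length(x) - nf + 1):length(x)] <-
      x[(length(x) - nf + 1):length(x)] * rev(ramp)
  }
  x
}

#' Generate a labeled synthetic corpus
#'
#' Draws per-speaker profiles around the [preset_profiles()] (relative
#' spread on jitter and shimmer, additive spread on HNR and F0) and
#' synthesizes one sustained vowel per speaker. The manifest records every
#' drawn parameter and the per-item seed, so the corpus is reproducible end
#' to end from `seed` alone.
#'
#' @param n_pd,n_hc Class sizes (the study corpus is 40 PD / 41 HC).
#' @param jitter_spread Relative sd of the per-speaker jitter/shimmer draw
#'   (default 0.15).
#' @param seed Integer RNG seed.
#' @param rate Sampling rate in Hz.
#' @param duration Recording duration in seconds.
#' @return A `labeled_corpus`: list of [audio_signal()]s and a `manifest`
#'   data.frame (one row per item: label, drawn parameters, item seed).
#' @export
make_corpus <- function(n_pd = 40, n_hc = 41, jitter_spread = 0.15,
                        seed = 1, rate = 8000, duration = 3) {
  if (n_pd < 1 || n_hc < 1) {
    dv_stop("dysvoice_error_bad_params", "class counts must be >= 1")
  }
  presets <- preset_profiles()
  with_seed(seed, {
    n <- n_pd + n_hc
    labels <- c(rep("PD", n_pd), rep("HC", n_hc))
    item_seeds <- sample.int(.Machine$integer.max - 1L, n)
    rows <- vector("list", n)
    signals <- vector("list", n)
    for (i in seq_len(n)) {
      p <- presets[[tolower(labels[i])]]
      prof <- voice_profile(
        f0_mean = min(400, max(80, p$f0_mean + rnorm(1, 0, 12))),
        f0_sd = max(0.2, p$f0_sd * (1 + 0.2 * rnorm(1))),
        jitter_pct = max(0.05, p$jitter_pct * (1 + jitter_spread * rnorm(1))),
        shimmer_pct = max(0.2, p$shimmer_pct * (1 + jitter_spread * rnorm(1))),
        hnr_db = p$hnr_db + rnorm(1, 0, 1),
        formants = p$formants * (1 + 0.04 * rnorm(3)),
        formant_bw = p$formant_bw,
        duration = duration, label = labels[i]
      )
      signals[[i]] <- synth_vowel(prof, rate = rate, seed = item_seeds[i])
      rows[[i]] <- data.frame(
        id = i, label = labels[i], f0_mean = prof$f0_mean,
        f0_sd = prof$f0_sd, jitter_pct = prof$jitter_pct,
        shimmer_pct = prof$shimmer_pct, hnr_db = prof$hnr_db,
        f1 = prof$formants[1], f2 = prof$formants[2], f3 = prof$formants[3],
        duration = duration, rate = rate, seed = item_seeds[i]
      )
    }
    structure(list(signals = signals, manifest = do.call(rbind, rows)),
              class = "labeled_corpus")
  })
}

#' @export
print.labeled_corpus <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat(sprintf("<labeled_corpus> %d items (%s)\n", nrow(x$manifest),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
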