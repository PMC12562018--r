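#' Autocorrelation pitch tracking
#'
#' Framewise fundamental-frequency estimation: per frame, the normalized
#' cross-correlation is evaluated over the lag range corresponding to
#' `range`, its maximum refined by parabolic interpolation, and the frame is
#' voiced when the normalized peak reaches `voicing_threshold`
#' (`f0 = rate / lag` at the peak; unvoiced frames get `f0 = 0`).
#'
#' @param signal An [audio_signal()].
#' @param params Frame geometry; defaults to 40 ms frames, 10 ms hop (pitch
#'   frames are longer than spectral frames so low-F0 lags keep support).
#' @param range Search range `c(fmin, fmax)` in Hz, default 75-500 Hz.
#' @param voicing_threshold Normalized-autocorrelation voicing cut, default 0.45.
#' @return A `pitch_track`: per-frame `f0` (Hz), `voicing` flag, frame
#'   center `times` (s), and the search range.
#' @export
track_f0 <- function(signal,
                     params = stft_params(signal$rate,
                                          frame_length = round(0.040 * signal$rate)),
                     range = c(75, 500),
                     voicing_threshold = 0.45) {
  stopifnot(inherits(signal, "audio_signal"))
  if (range[1] >= range[2] || range[2] >= signal$rate / 2) {
    dv_stop("dysvoice_error_bad_range",
            "need fmin < fmax < rate/2, got [%g, %g]", range[1], range[2])
  }
  frames <- frame_signal(signal$samples, params$frame_length, params$hop)
  n <- params$frame_length
  lag_min <- max(2L, floor(signal$rate / range[2]))
  lag_max <- min(n - 2L, ceiling(signal$rate / range[1]))
  nfft <- next_pow2(2L * n)
  global_rms <- sqrt(mean(signal$samples^2))
  lags <- lag_min:lag_max
  # pass 1: per-frame normalized-autocorrelation candidates (local maxima)
  cands <- apply(frames, 2, function(x) {
    x <- x - mean(x)
    e0 <- sum(x^2)
    if (e0 <= (1e-4 * global_rms)^2 * n || e0 == 0) {
      return(list(lag = numeric(0), r = numeric(0)))
    }
    ps <- Mod(fft(c(x, numeric(nfft - n))))^2
    ac <- Re(fft(ps, inverse = TRUE)) / nfft
    cs <- cumsum(x^2)
    e1 <- cs[n - lags]                       # energy of x[1..N-lag]
    e2 <- cs[n] - cs[lags]                   # energy of x[lag+1..N]
    r <- ac[lags + 1] / sqrt(pmax(e1 * e2, 1e-300))
    lm <- unique(c(which(diff(sign(diff(r))) == -2) + 1, which.max(r)))
    lm <- lm[r[lm] >= voicing_threshold]
    lag_ref <- vapply(lm, function(pk) {
      if (pk > 1 && pk < length(r)) {
        lags[pk] + parabolic_peak(r[pk - 1], r[pk], r[pk + 1])$delta
      } else as.numeric(lags[pk])
    }, numeric(1))
    list(lag = lag_ref, r = r[lm])
  }, simplify = FALSE)
  # pass 2: a sustained vowel has one F0, so each frame keeps the candidate
  # consistent with a recording-level cepstral reference (the quefrency
  # peak of the average log spectrum), which is immune to the octave flips
  # that plague frame-local autocorrelation peaks in noisy, jittery voices
  med <- cepstral_f0(signal, range)
  f0 <- vapply(cands, function(cd) {
    if (!length(cd$lag)) return(0)
    fs <- signal$rate / cd$lag
    near <- which(fs >= 0.75 * med & fs <= 1.3 * med)
    if (length(near)) fs[near[which.max(cd$r[near])]] else 0
  }, numeric(1))
  f0[f0 < range[1] | f0 > range[2]] <- 0
  voiced <- f0 > 0
  times <- ((seq_len(ncol(frames)) - 1) * params$hop +
              params$frame_length / 2) / signal$rate
  structure(list(f0 = f0, voicing = voiced, times = times,
                 search_range = range, params = params),
            class = "pitch_track")
}

#' Glottal cycle extraction
#'
#' F0-guided peak picking: starting from the largest waveform peak in the
#' voiced region, successive cycle marks are placed at the maximum sample
#' within a window of 0.7-1.3 expected periods of the previous mark, with
#' parabolic sub-sample refinement. Periods are successive mark differences;
#' amplitudes are the (interpolated) per-cycle peak heights. Occasional
#' marking failures (a skipped or spurious cycle) are censored: periods
#' outside 0.65-1.45 of the median are dropped and the sequence is split
#' into contiguous runs (`runs`) so that cycle-to-cycle statistics never
#' difference across a gap.
#'
#' @param signal An [audio_signal()].
#' @param track A `pitch_track` from [track_f0()] with >= 3 voiced frames.
#' @return A `pitch_cycles` object: `periods` (s), per-cycle `amplitudes`,
#'   the run index `runs`, and the fractional-sample `marks`.
#' @export
extract_cycles <- function(signal, track = track_f0(signal)) {
  stopifnot(inherits(signal, "audio_signal"), inherits(track, "pitch_track"))
  if (sum(track$voicing) < 3) {
    dv_stop("dysvoice_error_unvoiced",
            "need at least 3 voiced frames, found %d", sum(track$voicing))
  }
  x <- signal$samples
  rate <- signal$rate
  vt <- track$times[track$voicing]
  lo <- max(1, floor((min(vt) - 0.02) * rate), round(0.02 * rate))
  hi <- min(length(x), ceiling((max(vt) + 0.02) * rate),
            length(x) - round(0.02 * rate))
  f0_fun <- stats::approxfun(track$times[track$voicing],
                             track$f0[track$voicing], rule = 2)
  seed_idx <- lo - 1 + which.max(x[lo:hi])
  march <- function(from, dir) {
    marks <- numeric(0)
    pos <- from
    repeat {
      period <- rate / f0_fun(pos / rate)
      center <- pos + dir * period
      w_lo <- floor(center - 0.3 * period)
      w_hi <- ceiling(center + 0.3 * period)
      if (w_lo < lo + 1 || w_hi > hi - 1) break
      win <- w_lo:w_hi
      pk <- win[which.max(x[win])]
      if (x[pk] <= 0) break
      pp <- parabolic_peak(x[pk - 1], x[pk], x[pk + 1])
      m <- pk + pp$delta
      marks <- c(marks, m)
      pos <- m
    }
    marks
  }
  pk0 <- seed_idx
  pp0 <- parabolic_peak(x[pk0 - 1], x[pk0], x[pk0 + 1])
  m0 <- pk0 + pp0$delta
  marks <- c(rev(march(m0, -1)), m0, march(m0, +1))
  if (length(marks) < 3) {
    dv_stop("dysvoice_error_unvoiced", "too few pitch cycles located")
  }
  # matched-filter refinement against the colored noise background: the
  # signal is weighted by the inverse square root of the noise PSD
  # (estimated as the between-harmonics periodogram floor), which is the
  # optimal pre-filter for timing estimation in colored noise. Amplitudes
  # are then re-measured on the raw waveform at the refined marks.
  f0_med <- median(track$f0[track$voicing])
  ref <- refine_marks(noise_weighted(x, rate, f0_med), marks, rate)
  marks <- ref$marks
  amps_all <- template_amplitudes(x, marks)
  periods0 <- diff(marks) / rate
  med <- median(periods0)
  # band is > 5 sd of even severe (4-5 %) physiological jitter, but censors
  # marking failures (skipped cycles, ringing-lobe misalignments)
  ok <- periods0 >= 0.8 * med & periods0 <= 1.25 * med
  if (sum(ok) < 2) {
    dv_stop("dysvoice_error_unvoiced", "pitch cycles too irregular to use")
  }
  runs0 <- cumsum(c(TRUE, !ok[-length(ok)]))
  structure(list(periods = periods0[ok],
                 amplitudes = amps_all[-length(amps_all)][ok],
                 runs = runs0[ok],
                 marks = marks, valid = ok, rate = rate,
                 measured = TRUE,
                 amp_noise_sd = attr(amps_all, "noise_sd")),
            class = "pitch_cycles")
}

# Design matrix of the pulse-superposition model: each column k holds the
# summed, amplitude-scaled, band-limited fractional shifts of pulse-shape
# sample k at every mark. Support spans -0.5..2.5 reference periods.
pulse_design <- function(x, marks, amps, t_ref) {
  n <- length(x)
  k_off <- seq(-round(0.5 * t_ref), round(2.5 * t_ref))
  K <- length(k_off)
  taps <- -5:6
  lanczos <- function(u) ifelse(abs(u) < 6, sinc(u) * sinc(u / 6), 0)
  B <- matrix(0, n, K)
  for (i in seq_along(marks)) {
    r0 <- floor(marks[i]); fr <- marks[i] - r0
    w <- lanczos(taps - fr)
    for (j in seq_along(taps)) {
      rows <- r0 + taps[j] + k_off
      okr <- rows >= 1 & rows <= n
      B[cbind(rows[okr], which(okr))] <-
        B[cbind(rows[okr], which(okr))] + amps[i] * w[j]
    }
  }
  list(B = B, k_off = k_off)
}

fit_pulse_shape <- function(B, x, region) {
  Br <- B[region, , drop = FALSE]
  M <- crossprod(Br)
  g <- solve(M + diag(ncol(B)) * (sum(diag(M)) / ncol(B)) * 1e-8,
             crossprod(Br, x[region]))
  as.numeric(g)
}

# Gauss-Newton refinement of the mark times under the superposition model:
# given the fitted pulse shape g, each mark moves by
# delta_i = -<residual, A_i g'(t - m_i)> / ||A_i g'||^2 (clamped). Returns
# the refined marks and the analytic timing-noise floor
# sd = sqrt(P_resid / ||A g'||^2) of a single mark estimate.
deconv_polish <- function(x, marks, n_iter = 2) {
  bf <- signal::butter(4, 0.85)
  x <- as.numeric(signal::filtfilt(bf, x))
  n <- length(x)
  t_ref <- median(diff(marks))
  amps <- template_amplitudes(x, marks)
  if (length(amps) >= 5) amps <- stats::runmed(amps, 5)
  lo <- max(1, floor(min(marks) - 0.5 * t_ref))
  hi <- min(n, ceiling(max(marks) + 2.5 * t_ref))
  region <- lo:hi
  d2_mean <- 1; p_res <- 0
  for (iter in seq_len(n_iter)) {
    des <- pulse_design(x, marks, amps, t_ref)
    g <- fit_pulse_shape(des$B, x, region)
    resid <- x - as.numeric(des$B %*% g)
    dg <- c(0, diff(g))
    d2 <- numeric(length(marks))
    delta <- numeric(length(marks))
    for (i in seq_along(marks)) {
      rows <- round(marks[i]) + des$k_off
      okr <- rows >= 1 & rows <= n
      d <- amps[i] * dg[okr]
      d2[i] <- sum(d^2)
      if (d2[i] > 0) delta[i] <- -sum(resid[rows[okr]] * d) / d2[i]
    }
    delta <- pmax(-0.5, pmin(0.5, delta))
    marks <- marks + delta
    p_res <- mean(resid[region]^2)
    d2_mean <- mean(d2[d2 > 0])
  }
  list(marks = marks, timing_sd = sqrt(p_res / max(d2_mean, 1e-300)))
}

# Recording-level F0 reference: lag of the maximum of the (circular)
# autocorrelation of the average log power spectrum within the search
# range -- the cepstral signature of harmonic spacing.
cepstral_f0 <- function(signal, range = c(75, 500)) {
  p <- stft_params(signal$rate, frame_length = round(0.04 * signal$rate),
                   fft_size = max(2048L, next_pow2(round(0.04 * signal$rate))))
  sp <- stft(signal, p)
  ls <- rowMeans(log(Mod(sp$values)^2 + 1e-12))
  full <- c(ls, rev(ls[2:(length(ls) - 1)]))
  ac <- Re(fft(full))
  lags <- floor(signal$rate / range[2]):ceiling(signal$rate / range[1])
  pk <- lags[which.max(ac[lags + 1])]
  if (pk > min(lags) && pk < max(lags)) {
    pk <- pk + parabolic_peak(ac[pk], ac[pk + 1], ac[pk + 2])$delta
  }
  signal$rate / pk
}

# Colored-noise matched-filter pre-weighting: divide the spectrum by the
# square root of the noise PSD, estimated as the running median of the
# periodogram over a 2.5-F0-wide band (medians ignore the narrow harmonic
# peaks, leaving the between-harmonics noise floor).
noise_weighted <- function(x, rate, f0) {
  n <- length(x)
  X <- fft(x)
  p <- Mod(X)^2
  bw <- max(31L, round(2.5 * f0 / (rate / n)))
  if (bw %% 2 == 0) bw <- bw + 1L
  sn <- stats::runmed(c(tail(p, bw), p, head(p, bw)), bw)[(bw + 1):(bw + n)]
  Re(fft(X / sqrt(pmax(sn, 1e-6 * max(sn))), inverse = TRUE)) / n
}

# Whitening by LPC inverse filtering (autocorrelation method).
lpc_whiten <- function(x, order = 12) {
  a <- lpc_autocor(x - mean(x), order)
  if (is.null(a)) return(x)
  e <- as.numeric(stats::filter(x, c(1, a), method = "convolution", sides = 1))
  e[is.na(e)] <- 0
  e
}

# Per-cycle amplitude as the least-squares scale of the mark-locked mean
# cycle waveform (noise averages out of both template and fit).
template_amplitudes <- function(x, marks) {
  t_ref <- median(diff(marks))
  tau <- (-max(3L, round(0.35 * t_ref))):(max(5L, round(0.85 * t_ref)))
  n <- length(x)
  r0 <- round(marks)
  usable <- r0 + min(tau) >= 1 & r0 + max(tau) + 1 <= n
  if (sum(usable) < 3) return(peak_height(x, marks))
  templ <- rowMeans(vapply(r0[usable], function(c0) x[c0 + tau],
                           numeric(length(tau))))
  tt2 <- max(sum(templ^2), 1e-300)
  res2 <- numeric(0)
  amps <- vapply(seq_along(marks), function(i) {
    if (!usable[i]) return(abs(peak_height(x, marks[i])))
    win <- x[r0[i] + tau]
    a <- sum(win * templ) / tt2
    res2[length(res2) + 1] <<- mean((win - a * templ)^2)
    abs(a)
  }, numeric(1))
  # standard error of the amplitude fit under its own residual noise:
  # sd(a_hat) = sqrt(P_resid / sum(templ^2))
  attr(amps, "noise_sd") <- sqrt(median(res2) / tt2)
  amps
}

# Cross-correlate each cycle against the mark-locked mean cycle waveform;
# returns parabolic sub-sample mark positions and template-fit amplitudes.
refine_marks <- function(x, marks, rate, n_iter = 3) {
  t_ref <- median(diff(marks))
  # asymmetric window: the pulse and its resonator ringing, stopping short
  # of the following pulse's peak (whose independent jitter would leak in)
  tau <- (-max(3L, round(0.35 * t_ref))):(max(5L, round(0.85 * t_ref)))
  smax <- max(2L, round(0.2 * t_ref))
  n <- length(x)
  amps <- NULL
  for (iter in seq_len(n_iter)) {
    r0 <- round(marks)
    usable <- r0 + min(tau) - smax >= 1 & r0 + max(tau) + smax + 1 <= n
    if (sum(usable) < 3) return(list(marks = marks,
                                     amps = peak_height(x, marks)))
    templ <- rowMeans(vapply(r0[usable], function(c0) x[c0 + tau],
                             numeric(length(tau))))
    tt2 <- sum(templ^2)
    amps <- numeric(length(marks))
    new_marks <- marks
    for (i in seq_along(marks)) {
      if (!usable[i]) { amps[i] <- abs(peak_height(x, marks[i])); next }
      cc <- vapply((-smax):smax, function(s) sum(x[r0[i] + s + tau] * templ),
                   numeric(1))
      pk <- which.max(cc)
      shift <- pk - smax - 1
      if (pk > 1 && pk < length(cc)) {
        shift <- shift + parabolic_peak(cc[pk - 1], cc[pk], cc[pk + 1])$delta
      }
      new_marks[i] <- r0[i] + shift
      amps[i] <- abs(cc[pk]) / tt2
    }
    marks <- new_marks
  }
  # final sub-sample pass: correlate each cycle against a bank of
  # band-limited fractionally shifted templates (0.05-sample grid); the
  # 3-point parabola's shift-dependent bias would otherwise dominate the
  # timing error budget
  r0 <- round(marks)
  usable <- r0 + min(tau) - 2 >= 1 & r0 + max(tau) + 2 <= n
  if (sum(usable) >= 3) {
    templ <- rowMeans(vapply(r0[usable], function(c0) x[c0 + tau],
                             numeric(length(tau))))
    templ <- templ * tukey_window(length(templ), 0.2)
    fine <- seq(-1, 1, by = 0.05)
    bank <- vapply(fine, function(s) shift_fft(templ, s), numeric(length(templ)))
    for (i in which(usable)) {
      win <- x[r0[i] + tau]
      cc <- crossprod(win, bank)
      # bank column s delays the template by s, matching a cycle whose
      # mark sits at r0 + s
      marks[i] <- r0[i] + fine[which.max(cc)]
    }
  }
  list(marks = marks, amps = amps)
}

# Exact band-limited fractional delay by FFT phase rotation (circular;
# callers taper the sequence so wrap-around is negligible).
shift_fft <- function(v, s) {
  n <- length(v)
  kk <- ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)
  ph <- exp(-2i * pi * kk * s / n)
  if (n %% 2 == 0) ph[n / 2 + 1] <- cos(pi * s)
  Re(fft(fft(v) * ph, inverse = TRUE)) / n
}

tukey_window <- function(n, alpha = 0.2) {
  w <- rep(1, n)
  edge <- max(1L, floor(alpha * n / 2))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(edge) - 0.5) / edge))
  w[seq_len(edge)] <- ramp
  w[(n - edge + 1):n] <- rev(ramp)
  w
}

# Interpolated |peak| height at fractional mark positions.
peak_height <- function(x, marks) {
  vapply(marks, function(m) {
    i <- round(m)
    pp <- parabolic_peak(x[i - 1], x[i], x[i + 1])
    abs(pp$height)
  }, numeric(1))
}

#' Jitter (relative, percent)
#'
#' Mean absolute cycle-to-cycle period difference, relative to the mean
#' period: `(1/(N-1)) * sum |T_i - T_{i+1}| / mean(T)`, in percent.
#' Scale-invariant; elevated in unstable (pathological) phonation.
#'
#' When the cycles come from [extract_cycles()] (flagged `measured`), the
#' statistic is debiased for cycle-mark measurement noise using the
#' autocovariance signature of the period-difference sequence: independent
#' period jitter contributes `(2s_T^2, -s_T^2, 0)` to the difference
#' autocovariances at lags (0, 1, 2) while white mark noise contributes
#' `(6s_m^2, -4s_m^2, s_m^2)`, so both variances are identified from the
#' data and the mark-noise part is removed under the Gaussian convention
#' `E|d| = sqrt(2/pi) sd(d)`. Hand-built cycle sequences evaluate the
#' printed formula verbatim.
#'
#' @param cycles A `pitch_cycles` object (>= 2 periods).
#' @return Jitter in percent (>= 0).
#' @export
jitter_percent <- function(cycles) {
  periods <- cycles$periods
  if (length(periods) < 2) {
    dv_stop("dysvoice_error_too_few_cycles", "need at least 2 periods")
  }
  d <- diffs_within_runs(periods, cycles$runs)
  if (!length(d)) {
    dv_stop("dysvoice_error_too_few_cycles", "no successive period pairs")
  }
  m <- mean(abs(d))
  if (isTRUE(cycles$measured) && length(d) >= 30) {
    cv <- function(k) {
      mean(d[seq_len(length(d) - k)] * d[seq_len(length(d) - k) + k]) -
        mean(d)^2
    }
    c0 <- cv(0); c1 <- cv(1); c2 <- cv(2)
    # least squares for (s_T^2, s_m^2) against the signature above
    A <- matrix(c(2, -1, 0, 6, -4, 1), 3, 2)
    th <- solve(crossprod(A), crossprod(A, c(c0, c1, c2)))
    s_t2 <- max(0, th[1])
    m <- sqrt(2 / pi) * sqrt(2 * s_t2)
  }
  100 * m / mean(periods)
}

# |successive differences| restricted to contiguous runs (no censoring gap).
successive_diffs <- function(v, runs) abs(diffs_within_runs(v, runs))

diffs_within_runs <- function(v, runs) {
  d <- diff(v)
  if (is.null(runs)) d else d[diff(runs) == 0]
}

#' Shimmer (relative, percent)
#'
#' Mean absolute cycle-to-cycle amplitude difference relative to the mean
#' amplitude, in percent. See [shimmer_db()] for the dB companion.
#'
#' The formula is evaluated on the extracted per-cycle amplitudes as
#' printed. Amplitude estimates carry measurement noise that grows as HNR
#' falls, so extracted shimmer includes a noise-dependent floor (documented
#' in the methods vignette); the clean-voice limit is exact.
#'
#' @param cycles A `pitch_cycles` object (>= 2 amplitudes).
#' @return Shimmer in percent (>= 0).
#' @export
shimmer_percent <- function(cycles) {
  a <- cycles$amplitudes
  if (length(a) < 2) {
    dv_stop("dysvoice_error_too_few_cycles", "need at least 2 amplitudes")
  }
  if (mean(a) <= 0) {
    dv_stop("dysvoice_error_degenerate", "mean cycle amplitude is zero")
  }
  d <- successive_diffs(a, cycles$runs)
  if (!length(d)) {
    dv_stop("dysvoice_error_too_few_cycles", "no successive amplitude pairs")
  }
  100 * mean(d) / mean(a)
}

#' Shimmer in decibels
#'
#' Mean absolute base-10 log amplitude ratio of consecutive cycles,
#' `mean |20 log10(A_{i+1} / A_i)|`.
#'
#' @inheritParams shimmer_percent
#' @return Shimmer in dB (>= 0).
#' @export
shimmer_db <- function(cycles) {
  a <- cycles$amplitudes
  if (length(a) < 2) {
    dv_stop("dysvoice_error_too_few_cycles", "need at least 2 amplitudes")
  }
  if (any(a <= 0)) {
    dv_stop("dysvoice_error_degenerate", "non-positive cycle amplitude")
  }
  r <- abs(20 * log10(a[-1] / a[-length(a)]))
  if (!is.null(cycles$runs)) r <- r[diff(cycles$runs) == 0]
  if (!length(r)) {
    dv_stop("dysvoice_error_too_few_cycles", "no successive amplitude pairs")
  }
  mean(r)
}

#' Harmonics-to-noise ratio
#'
#' `HNR = 10 log10(P_harmonic / P_noise)`. The periodic component is
#' estimated by pitch-synchronous deconvolution: the voiced waveform is
#' modeled as a sum of amplitude-scaled copies of one common pulse response
#' placed at the extracted cycle marks, and the response is solved for by
#' least squares. The reconstruction is the harmonic component; its
#' residual over the interior voiced region is the noise. Because the pulse
#' copies follow the actual (jittered) mark times, cycle-timing
#' irregularity is absorbed into the harmonic component rather than
#' inflating the noise estimate.
#'
#' @param signal An [audio_signal()].
#' @param track Optional `pitch_track` (computed if missing).
#' @param cycles Optional `pitch_cycles` (computed if missing).
#' @return HNR in dB.
#' @export
hnr_db <- function(signal, track = NULL, cycles = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.null(cycles)) {
    if (is.null(track)) track <- track_f0(signal)
    if (!any(track$voicing)) {
      dv_stop("dysvoice_error_unvoiced", "no voiced frames")
    }
    cycles <- extract_cycles(signal, track)
  }
  marks <- cycles$marks
  n_cyc <- length(marks) - 1
  if (n_cyc < 8) {
    dv_stop("dysvoice_error_too_few_cycles", "too few cycles for HNR")
  }
  # one damped Gauss-Newton pass refines the marks under the model itself;
  # the noise it absorbs (one degree of freedom per cycle) is added back
  # below
  marks <- deconv_polish(signal$samples, marks, n_iter = 1)$marks
  # zero-phase band limit just below Nyquist: the topmost band carries
  # negligible harmonic energy but concentrates resampling/interpolation
  # artifacts that would otherwise dominate the residual
  bf <- signal::butter(4, 0.85)
  x <- as.numeric(signal::filtfilt(bf, signal$samples))
  n <- length(x)
  t_ref <- median(diff(marks))
  # median-smoothed amplitudes: per-cycle amplitude fits correlate with the
  # in-cycle noise and would otherwise absorb noise into the harmonic part
  amps <- template_amplitudes(x, marks)
  if (length(amps) >= 5) amps <- stats::runmed(amps, 5)
  des <- pulse_design(x, marks, amps, t_ref)
  valid <- if (is.null(cycles$valid)) rep(TRUE, n_cyc) else cycles$valid
  vset <- which(valid)
  if (length(vset) < 6) {
    dv_stop("dysvoice_error_too_few_cycles", "too few regular cycles for HNR")
  }
  interior <- vset[vset > min(vset) + 1 & vset < max(vset) - 1]
  region <- unlist(lapply(interior, function(i) {
    ceiling(marks[i]):floor(marks[i + 1])
  }))
  region <- region[region >= 1 & region <= n]
  g <- fit_pulse_shape(des$B, x, region)
  harm <- as.numeric(des$B[region, , drop = FALSE] %*% g)
  resid <- x[region] - harm
  # degrees-of-freedom correction: the fitted pulse shape, the per-cycle
  # timing refinement and the (smoothed) amplitudes each absorb noise
  p_fit <- ncol(des$B) + n_cyc + n_cyc / 5
  dof <- max(0.5, 1 - p_fit / length(region))
  p_harm <- max(mean(harm^2), 1e-300)
  p_noise <- max(mean(resid^2) / dof, 1e-300)
  10 * log10(p_harm / p_noise)
}
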