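# Mel-scale helpers (HTK convention).
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param n_mels Number of triangular filters.
#' @param nfft FFT size the filters act on (one-sided bins `nfft/2 + 1`).
#' @param rate Sampling rate in Hz.
#' @param fmin,fmax Band edges in Hz (default 0 .. rate/2).
#' @return Matrix `n_mels x (nfft/2 + 1)` of filter weights.
#' @export
mel_filterbank <- function(n_mels, nfft, rate, fmin = 0, fmax = rate / 2) {
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  freqs <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ctr <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / max(ctr - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ctr, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' MFCCs with delta and delta-delta dynamics
#'
#' Per frame: power spectrum -> mel filterbank energies `E_m` -> log -> the
#' cosine transform `MFCC[n] = sum_m log(E_m) cos(pi * n * (m - 0.5) / M)`
#' for `n = 0 .. n_coeffs - 1`. Temporal derivatives use the regression
#' `delta_c_t = sum_{n=1}^{N} n (c_{t+n} - c_{t-n}) / (2 sum n^2)` with
#' replicated edges; the delta-delta track is the delta of the delta.
#'
#' @param signal An [audio_signal()].
#' @param params An [stft_params()].
#' @param n_coeffs Number of cepstral coefficients (default 13, incl. 0th).
#' @param n_mels Number of mel filters (default 40; must be >= n_coeffs).
#' @param delta_width Regression half-width N (default 2).
#' @return A list of three `n_coeffs x n_frames` matrices: `mfcc`, `delta`,
#'   `delta2`.
#' @export
mfcc_stack <- function(signal, params = stft_params(signal$rate),
                       n_coeffs = 13, n_mels = 40, delta_width = 2) {
  if (n_coeffs > n_mels) {
    dv_stop("dysvoice_error_bad_params", "n_coeffs must be <= n_mels")
  }
  spec <- stft(signal, params)
  power <- Mod(spec$values)^2
  fb <- mel_filterbank(n_mels, params$fft_size, signal$rate)
  energies <- pmax(fb %*% power, 1e-10)
  loge <- log(energies)
  m <- seq_len(n_mels)
  dct <- vapply(0:(n_coeffs - 1),
                function(n) cos(pi * n * (m - 0.5) / n_mels),
                numeric(n_mels))
  cc <- t(dct) %*% loge                       # n_coeffs x n_frames
  d1 <- delta_features(cc, delta_width)
  list(mfcc = cc, delta = d1, delta2 = delta_features(d1, delta_width))
}

#' Delta (regression) features
#'
#' @param coeffs Coefficient matrix, tracks in rows, frames in columns.
#' @param width Regression half-width N.
#' @return Matrix of the same shape.
#' @export
delta_features <- function(coeffs, width = 2) {
  coeffs <- as.matrix(coeffs)
  n_t <- ncol(coeffs)
  pad <- cbind(coeffs[, rep(1, width), drop = FALSE], coeffs,
               coeffs[, rep(n_t, width), drop = FALSE])
  denom <- 2 * sum((1:width)^2)
  out <- matrix(0, nrow(coeffs), n_t)
  for (n in seq_len(width)) {
    out <- out + n * (pad[, (1 + width + n):(n_t + width + n), drop = FALSE] -
                      pad[, (1 + width - n):(n_t + width - n), drop = FALSE])
  }
  out / denom
}

#' Log-power mel spectrogram at a fixed model-input geometry
#'
#' Power mel spectrogram, dB-compressed (`10 log10(S / max S)`, floored at
#' `db_floor`), and linearly resampled along time to exactly `n_frames`
#' frames so every recording yields the same `n_mels x n_frames` grid
#' (defaults 128 x 40, the classifier input geometry).
#'
#' @param signal An [audio_signal()].
#' @param n_mels Mel bands (default 128).
#' @param n_frames Output frames (default 40).
#' @param params STFT geometry; the default widens the FFT so that 128 mel
#'   filters have bin support.
#' @param db_floor Clip level in dB (default -80).
#' @return A `mel_spectrogram`: `values` (`n_mels x n_frames`, dB), band
#'   center frequencies `mel_centers_hz`, and the geometry.
#' @export
mel_spectrogram <- function(signal, n_mels = 128, n_frames = 40,
                            params = NULL, db_floor = -80) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!length(signal$samples)) {
    dv_stop("dysvoice_error_empty_audio", "empty signal")
  }
  if (is.null(params)) {
    fl <- round(0.025 * signal$rate)
    params <- stft_params(signal$rate, frame_length = fl,
                          fft_size = max(512L, next_pow2(fl)))
  }
  spec <- stft(signal, params)
  fb <- mel_filterbank(n_mels, params$fft_size, signal$rate)
  S <- fb %*% (Mod(spec$values)^2)
  ref <- max(S)
  db <- if (ref <= 0) matrix(db_floor, nrow(S), ncol(S)) else
    pmax(10 * log10(pmax(S, 1e-300) / ref), db_floor)
  # linear time resampling onto the fixed frame count
  src <- seq(0, 1, length.out = ncol(db))
  dst <- seq(0, 1, length.out = n_frames)
  vals <- t(apply(db, 1, function(row) {
    if (length(row) == 1) rep(row, n_frames) else approx(src, row, dst)$y
  }))
  mel_pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(signal$rate / 2),
                           length.out = n_mels + 2))
  structure(list(values = vals, mel_centers_hz = mel_pts[2:(n_mels + 1)],
                 n_mels = n_mels, n_frames = n_frames, rate = signal$rate,
                 db_floor = db_floor),
            class = "mel_spectrogram")
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram> %d bands x %d frames, %g Hz, floor %g dB\n",
              x$n_mels, x$n_frames, x$rate, x$db_floor))
  invisible(x)
}
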