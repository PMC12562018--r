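#' Spectral gate parameters
#'
#' Controls for the spectral-gating denoiser: threshold multiplier `k`,
#' sub-threshold gain `alpha`, and the number of leading noise-only frames
#' used to estimate the noise floor. Defaults are k = 1.5, alpha = 0.1,
#' T = 10 frames.
#'
#' The comparison of a coefficient against the threshold `k * P_N(f)` can be
#' made in the power domain (`|X|^2 <= k * P_N`, the default, dimensionally
#' consistent with a power-spectral noise floor) or literally on magnitudes
#' (`|X| <= k * P_N`), selected by `domain`.
#'
#' @param k Threshold multiplier (> 0).
#' @param alpha Gain applied below threshold (0 <= alpha <= 1).
#' @param noise_frames Number of leading frames treated as noise-only.
#' @param domain `"power"` or `"magnitude"` comparison domain.
#' @return A `gate_params` object.
#' @export
gate_params <- function(k = 1.5, alpha = 0.1, noise_frames = 10,
                        domain = c("power", "magnitude")) {
  if (k <= 0) dv_stop("dysvoice_error_bad_params", "k must be > 0")
  if (alpha < 0 || alpha > 1) {
    dv_stop("dysvoice_error_bad_params", "alpha must lie in [0, 1]")
  }
  if (noise_frames < 1) {
    dv_stop("dysvoice_error_bad_params", "noise_frames must be >= 1")
  }
  structure(list(k = k, alpha = alpha, noise_frames = as.integer(noise_frames),
                 domain = match.arg(domain)),
            class = "gate_params")
}

#' Estimate the noise power spectrum from leading frames
#'
#' Averages the squared STFT magnitudes of the first `noise_frames` frames,
#' which are assumed noise-only (the recording-head-is-silent contract; no
#' automatic silence detection is attempted):
#' `P_N(f) = (1/T) * sum_t |X(t, f)|^2`.
#'
#' @param spec A `spectrogram` from [stft()].
#' @param noise_frames Number of leading frames T to average.
#' @return A `noise_profile` with per-bin `psd` and `n_frames_used`.
#' @export
estimate_noise_psd <- function(spec, noise_frames = 10) {
  stopifnot(inherits(spec, "spectrogram"))
  if (ncol(spec$values) < noise_frames) {
    dv_stop("dysvoice_error_too_few_frames",
            "spectrogram has %d frames, need at least %d",
            ncol(spec$values), noise_frames)
  }
  psd <- rowMeans(Mod(spec$values[, seq_len(noise_frames), drop = FALSE])^2)
  structure(list(psd = psd, n_frames_used = as.integer(noise_frames)),
            class = "noise_profile")
}

#' Apply a spectral gate
#'
#' Coefficients above the per-bin noise threshold `T(f) = k * P_N(f)` pass
#' unchanged (gain 1); coefficients at or below it are multiplied by
#' `alpha`. The gain is real, so phase is never altered.
#'
#' @param spec A `spectrogram`.
#' @param noise A `noise_profile` on the same bin grid.
#' @param gate A [gate_params()].
#' @return The gated `spectrogram`.
#' @export
spectral_gate <- function(spec, noise, gate = gate_params()) {
  stopifnot(inherits(spec, "spectrogram"), inherits(noise, "noise_profile"))
  if (length(noise$psd) != nrow(spec$values)) {
    dv_stop("dysvoice_error_grid_mismatch",
            "noise profile has %d bins but spectrogram has %d",
            length(noise$psd), nrow(spec$values))
  }
  threshold <- gate$k * noise$psd
  level <- if (gate$domain == "power") Mod(spec$values)^2 else Mod(spec$values)
  gain <- ifelse(level > threshold, 1, gate$alpha)
  spec$values <- spec$values * gain
  spec
}

#' Spectral-gating noise reduction
#'
#' Full denoising chain: peak-normalize, STFT, noise-floor estimate from the
#' leading frames, threshold gate, inverse STFT, re-normalize. The output
#' has exactly the input length. Requires a noise-only head of at least
#' `noise_frames` frames in the recording.
#'
#' @param signal An [audio_signal()].
#' @param params An [stft_params()]; defaults derived from the signal rate.
#' @param gate A [gate_params()].
#' @return The denoised [audio_signal()].
#' @export
denoise <- function(signal, params = stft_params(signal$rate),
                    gate = gate_params()) {
  stopifnot(inherits(signal, "audio_signal"))
  n <- length(signal$samples)
  need <- (gate$noise_frames - 1) * params$hop + params$frame_length
  if (n < need) {
    dv_stop("dysvoice_error_short_signal",
            "signal too short for %d noise frames", gate$noise_frames)
  }
  sig <- normalize(signal)
  # tail padding so the frame grid covers every input sample
  sig$samples <- c(sig$samples, numeric(params$frame_length))
  spec <- stft(sig, params)
  noise <- estimate_noise_psd(spec, gate$noise_frames)
  gated <- spectral_gate(spec, noise, gate)
  out <- istft(gated, length_out = n)
  out$label <- signal$label
  if (max(abs(out$samples)) > 0) out <- normalize(out)
  out
}
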