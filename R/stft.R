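#' STFT analysis parameters
#'
#' Frame geometry for all short-time analyses. Defaults are the standard
#' speech-analysis values: 25 ms frames, 10 ms hop, periodic Hann window,
#' FFT size the next power of two above the frame length.
#'
#' @param rate Sampling rate in Hz used to derive sample counts.
#' @param frame_length Frame length in samples.
#' @param hop Hop size in samples (0 < hop <= frame_length).
#' @param window Taper name; currently `"hann"`.
#' @param fft_size FFT length in samples (>= frame_length).
#' @return An `stft_params` object.
#' @export
stft_params <- function(rate = 8000,
                        frame_length = round(0.025 * rate),
                        hop = round(0.010 * rate),
                        window = "hann",
                        fft_size = next_pow2(frame_length)) {
  if (hop <= 0 || hop > frame_length || frame_length > fft_size) {
    dv_stop("dysvoice_error_bad_params",
            "need 0 < hop <= frame_length <= fft_size")
  }
  window <- match.arg(window, "hann")
  structure(list(frame_length = as.integer(frame_length),
                 hop = as.integer(hop),
                 window = window,
                 fft_size = as.integer(fft_size)),
            class = "stft_params")
}

#' Short-time Fourier transform
#'
#' One-sided complex STFT: frame `t` covers samples
#' `[t*hop, t*hop + frame_length)`; each frame is Hann-windowed, zero-padded
#' to `fft_size` and transformed. Bins run 0..fft_size/2.
#'
#' @param signal An [audio_signal()].
#' @param params An [stft_params()].
#' @return A `spectrogram`: complex matrix `values` (bins x frames), the
#'   parameters, the sampling rate and the bin frequencies `freqs` (Hz).
#' @export
stft <- function(signal, params = stft_params(signal$rate)) {
  stopifnot(inherits(signal, "audio_signal"), inherits(params, "stft_params"))
  frames <- frame_signal(signal$samples, params$frame_length, params$hop)
  w <- hann_window(params$frame_length)
  frames <- frames * w
  nfft <- params$fft_size
  if (nfft > params$frame_length) {
    frames <- rbind(frames, matrix(0, nfft - params$frame_length, ncol(frames)))
  }
  spec <- stats::mvfft(frames)[seq_len(nfft / 2 + 1), , drop = FALSE]
  structure(list(values = spec, params = params, rate = signal$rate,
                 freqs = (0:(nfft / 2)) * signal$rate / nfft),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames @ %g Hz (frame %d, hop %d)\n",
              nrow(x$values), ncol(x$values), x$rate,
              x$params$frame_length, x$params$hop))
  invisible(x)
}

#' Inverse short-time Fourier transform
#'
#' Least-squares overlap-add reconstruction (synthesis frames re-windowed
#' and normalized by the summed squared window), which reconstructs any
#' signal whose STFT was taken with the same parameters to within numerical
#' round-off for any hop with full window coverage.
#'
#' @param spec A `spectrogram` from [stft()].
#' @param length_out Optional output length in samples (pad/crop).
#' @return An [audio_signal()].
#' @export
istft <- function(spec, length_out = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  p <- spec$params
  nfft <- p$fft_size
  full <- rbind(spec$values,
                Conj(spec$values[(nfft / 2):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nfft
  frames <- frames[seq_len(p$frame_length), , drop = FALSE]
  w <- hann_window(p$frame_length)
  n_frames <- ncol(frames)
  n <- (n_frames - 1) * p$hop + p$frame_length
  y <- numeric(n)
  wsum <- numeric(n)
  for (t in seq_len(n_frames)) {
    idx <- ((t - 1) * p$hop + 1):((t - 1) * p$hop + p$frame_length)
    y[idx] <- y[idx] + frames[, t] * w
    wsum[idx] <- wsum[idx] + w^2
  }
  ok <- wsum > 1e-10
  y[ok] <- y[ok] / wsum[ok]
  if (!is.null(length_out)) {
    y <- if (length(y) >= length_out) y[seq_len(length_out)] else
      c(y, numeric(length_out - length(y)))
  }
  audio_signal(y, spec$rate)
}
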