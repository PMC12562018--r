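#' Audio signal container
#'
#' A mono waveform with its sampling rate and an optional class label.
#' Amplitudes are dimensionless; after [normalize()] the peak absolute
#' amplitude is at most 1.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (> 0).
#' @param label Optional class tag: `"PD"`, `"HC"` or `"unknown"`.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate, label = "unknown") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    dv_stop("dysvoice_error_bad_rate", "sampling rate must be a single value > 0")
  }
  if (length(samples) && !all(is.finite(samples))) {
    dv_stop("dysvoice_error_nonfinite", "audio samples must all be finite")
  }
  label <- match.arg(label, c("unknown", "PD", "HC"))
  structure(list(samples = samples, rate = rate, label = label),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), label=%s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$label))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

duration <- function(signal) length(signal$samples) / signal$rate

#' Peak-normalize a waveform to [-1, 1]
#'
#' Divides by the maximum absolute amplitude. An all-zero signal is returned
#' unchanged (documented degenerate case); normalization is idempotent and
#' invariant to positive rescaling of the input.
#'
#' @param signal An [audio_signal()].
#' @return The normalized `audio_signal`.
#' @export
normalize <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!length(signal$samples)) {
    dv_stop("dysvoice_error_empty_audio", "cannot normalize an empty signal")
  }
  peak <- max(abs(signal$samples))
  if (peak > 0) signal$samples <- signal$samples / peak
  signal
}

#' Fixed-length segmentation policy
#'
#' Recordings are forced to a uniform duration before modeling: shorter
#' inputs are padded at the tail, longer ones truncated. The default keeps
#' the head of the recording, where sustained phonation carries its onset.
#'
#' @param target_duration Target duration in seconds (> 0). Default 3 s.
#' @param pad_value Amplitude used for padding (default 0).
#' @param mode `"truncate-head"` keeps the first `target_duration` seconds;
#'   `"truncate-center"` keeps a centered window.
#' @return A `segment_policy` object.
#' @export
segment_policy <- function(target_duration = 3, pad_value = 0,
                           mode = c("truncate-head", "truncate-center")) {
  if (!is.numeric(target_duration) || target_duration <= 0) {
    dv_stop("dysvoice_error_bad_policy", "target_duration must be > 0")
  }
  structure(list(target_duration = target_duration, pad_value = pad_value,
                 mode = match.arg(mode)),
            class = "segment_policy")
}

#' Enforce a fixed signal length
#'
#' @param signal An [audio_signal()].
#' @param policy A [segment_policy()].
#' @return An `audio_signal` of exactly `round(target_duration * rate)`
#'   samples. Idempotent.
#' @export
segment_fixed <- function(signal, policy = segment_policy()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(policy, "segment_policy"))
  n_target <- round(policy$target_duration * signal$rate)
  x <- signal$samples
  n <- length(x)
  if (n > n_target) {
    x <- switch(policy$mode,
      "truncate-head" = x[seq_len(n_target)],
      "truncate-center" = {
        start <- floor((n - n_target) / 2) + 1
        x[start:(start + n_target - 1)]
      })
  } else if (n < n_target) {
    x <- c(x, rep(policy$pad_value, n_target - n))
  }
  signal$samples <- x
  signal
}

#' Resample a waveform
#'
#' Polyphase anti-aliased resampling (via `signal::resample`); used to map
#' heterogeneous corpora (e.g. 44.1 kHz mobile and 8 kHz telephone
#' recordings) onto one canonical analysis rate.
#'
#' @param signal An [audio_signal()].
#' @param target_rate New sampling rate in Hz.
#' @return An `audio_signal` at `target_rate`.
#' @export
resample_audio <- function(signal, target_rate) {
  stopifnot(inherits(signal, "audio_signal"))
  if (target_rate <= 0) dv_stop("dysvoice_error_bad_rate", "target_rate must be > 0")
  if (target_rate == signal$rate) return(signal)
  # rational approximation of the rate ratio, capped to keep filters small
  fr <- gmp_ratio(target_rate, signal$rate)
  y <- signal::resample(signal$samples, fr$p, fr$q)
  audio_signal(as.numeric(y), target_rate, signal$label)
}

# Small-denominator rational approximation p/q ~= a/b.
gmp_ratio <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  ai <- round(a); bi <- round(b)
  if (abs(a - ai) < 1e-9 && abs(b - bi) < 1e-9) {
    d <- g(ai, bi)
    return(list(p = ai / d, q = bi / d))
  }
  # continued-fraction fallback for non-integer rates
  r <- a / b
  best <- c(1, 1)
  for (q in 1:1000) {
    p <- round(r * q)
    if (abs(p / q - r) < 1e-9) { best <- c(p, q); break }
  }
  list(p = best[1], q = best[2])
}
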