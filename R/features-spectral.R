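#' Zero crossing rate
#'
#' Fraction of adjacent sample pairs whose product is negative:
#' `ZCR = (1/(N-1)) * sum 1{x[n] * x[n-1] < 0}`. 0 for a constant-sign
#' frame, 1 for a strictly alternating one; high values indicate unvoiced
#' or noisy sound.
#'
#' @param frame Numeric vector of at least 2 samples.
#' @return A fraction in [0, 1].
#' @export
zero_crossing_rate <- function(frame) {
  n <- length(frame)
  if (n < 2) dv_stop("dysvoice_error_short_frame", "need at least 2 samples")
  sum(frame[-1] * frame[-n] < 0) / (n - 1)
}

#' Framewise spectral shape descriptors
#'
#' Centroid (magnitude-weighted mean frequency), bandwidth (magnitude-
#' weighted standard deviation around the centroid), flatness (geometric /
#' arithmetic mean of magnitudes: 0 for a pure tone, 1 for white noise) and
#' sub-band spectral contrast (mean peak-minus-valley log-magnitude
#' difference over octave-spaced sub-bands; peaks/valleys are the top and
#' bottom quintile means within each band).
#'
#' @param spectrum Non-negative magnitude vector for one frame.
#' @param freqs Bin frequencies in Hz, same length.
#' @param n_bands Number of contrast sub-bands (octave-spaced, default 6).
#' @return A list with `centroid`, `bandwidth`, `flatness`, `contrast` and
#'   `degenerate` (`TRUE` with all-`NA` descriptors for an all-zero
#'   spectrum; never silent NaNs).
#' @export
spectral_descriptors <- function(spectrum, freqs, n_bands = 6) {
  stopifnot(length(spectrum) == length(freqs))
  if (any(spectrum < 0)) {
    dv_stop("dysvoice_error_bad_spectrum", "magnitudes must be non-negative")
  }
  total <- sum(spectrum)
  if (total <= 0) {
    return(list(centroid = NA_real_, bandwidth = NA_real_,
                flatness = NA_real_, contrast = NA_real_, degenerate = TRUE))
  }
  centroid <- sum(freqs * spectrum) / total
  bandwidth <- sqrt(sum((freqs - centroid)^2 * spectrum) / total)
  # flatness on strictly positive support; zeros drive the geometric mean
  # (and hence flatness) to its pure-tone limit of 0
  flatness <- if (any(spectrum == 0)) 0 else
    exp(mean(log(spectrum))) / mean(spectrum)
  contrast <- spectral_contrast(spectrum, freqs, n_bands)
  list(centroid = centroid, bandwidth = bandwidth, flatness = flatness,
       contrast = contrast, degenerate = FALSE)
}

# Octave-spaced band edges starting one octave below Nyquist/2^(n_bands-1).
contrast_band_edges <- function(fmax, n_bands) {
  upper <- fmax * 2^(-(seq(n_bands - 1, 0)))
  c(0, upper)
}

spectral_contrast <- function(spectrum, freqs, n_bands = 6, eps = 1e-10) {
  edges <- contrast_band_edges(max(freqs), n_bands)
  logmag <- log10(spectrum + eps)
  vals <- vapply(seq_len(n_bands), function(b) {
    sel <- freqs > edges[b] & freqs <= edges[b + 1]
    if (b == 1) sel <- sel | freqs == 0
    v <- sort(logmag[sel])
    if (!length(v)) return(NA_real_)
    q <- max(1, round(length(v) / 5))
    mean(tail(v, q)) - mean(head(v, q))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
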