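#' Formant estimation from LPC roots
#'
#' Fits a linear-prediction polynomial `A(z) = 1 + sum a_k z^-k` by the
#' autocorrelation method (after light pre-emphasis) and reads formants off
#' the complex roots: roots inside the unit circle with positive imaginary
#' part map to candidate resonances at `angle * rate / (2*pi)` Hz with
#' bandwidth `-rate/pi * log |r|`. Candidates are bandwidth-filtered
#' (< `max_bandwidth`) and sorted ascending; the first three are F1-F3.
#'
#' @param frame Numeric sample block (>= 2 * order samples).
#' @param rate Sampling rate in Hz.
#' @param order LPC order; default the classic `2 + rate/1000` rule.
#' @param max_bandwidth Root acceptance bandwidth in Hz (default 400).
#' @param preemphasis First-order pre-emphasis coefficient.
#' @return A list: `formants` (named F1-F3 vector, NA where unavailable),
#'   `bandwidths`, and `reliable` (FALSE when fewer than 3 narrow-bandwidth
#'   roots exist, e.g. on noise).
#' @export
formants_lpc <- function(frame, rate, order = round(2 + rate / 1000),
                         max_bandwidth = 400, preemphasis = 0.97) {
  if (length(frame) < 2 * order) {
    dv_stop("dysvoice_error_short_frame",
            "frame of %d samples too short for LPC order %d",
            length(frame), order)
  }
  if (order < 8) dv_stop("dysvoice_error_bad_params", "LPC order must be >= 8")
  x <- frame - mean(frame)
  x <- c(x[1], x[-1] - preemphasis * x[-length(x)])
  x <- x * hann_window(length(x))
  a <- lpc_autocor(x, order)
  if (is.null(a)) {
    dv_stop("dysvoice_error_degenerate", "degenerate frame (no LPC solution)")
  }
  # roots of z^p * A(z): coefficients from z^0 upward are rev(c(1, a))
  rts <- polyroot(rev(c(1, a)))
  ang <- Arg(rts)
  keep <- ang > 0 & Mod(rts) < 1
  freq <- ang[keep] * rate / (2 * pi)
  bw <- -rate / pi * log(pmax(Mod(rts[keep]), 1e-12))
  ok <- freq > 60 & freq < rate / 2 - 60 & bw < max_bandwidth
  freq <- freq[ok]; bw <- bw[ok]
  ord <- order(freq)
  freq <- freq[ord]; bw <- bw[ord]
  out <- rep(NA_real_, 3); outbw <- rep(NA_real_, 3)
  n <- min(3, length(freq))
  if (n > 0) { out[1:n] <- freq[1:n]; outbw[1:n] <- bw[1:n] }
  names(out) <- names(outbw) <- c("F1", "F2", "F3")
  list(formants = out, bandwidths = outbw, reliable = n == 3)
}

# Autocorrelation-method LPC with a tiny ridge for numerical safety.
lpc_autocor <- function(x, order) {
  n <- length(x)
  r <- vapply(0:order, function(k) sum(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  if (r[1] <= 0) return(NULL)
  R <- toeplitz(r[1:order]) + diag(order) * r[1] * 1e-9
  as.numeric(solve(R, -r[2:(order + 1)]))
}
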