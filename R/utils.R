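# Internal helpers shared across modules.

# Condition constructor: all package errors carry a distinct class so callers
# can condition on them.
dv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dysvoice_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Evaluate an expression with a locally-seeded RNG, restoring the caller's
# RNG state afterwards (all stochastic entry points funnel through this).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Periodic Hann taper (analysis/synthesis window for the STFT).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Slice a waveform into overlapping frames; returns frame_length x n_frames.
frame_signal <- function(x, frame_length, hop) {
  n <- length(x)
  if (n < frame_length) {
    dv_stop("dysvoice_error_short_signal",
            "signal (%d samples) shorter than one frame (%d samples)",
            n, frame_length)
  }
  n_frames <- floor((n - frame_length) / hop) + 1
  idx <- outer(seq_len(frame_length), (seq_len(n_frames) - 1) * hop, `+`)
  matrix(x[idx], nrow = frame_length)
}

# Parabolic interpolation of a discrete peak: given y[-1], y[0], y[+1]
# returns fractional offset in (-0.5, 0.5) and interpolated height.
parabolic_peak <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (ym1 - yp1) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(delta = delta, height = y0 - 0.25 * (ym1 - yp1) * delta)
}
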