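feature_schema_version <- "1.0"

mfcc_stat_names <- function(n_coeffs = 13) {
  base <- c(paste0("mfcc", 0:(n_coeffs - 1)),
            paste0("dmfcc", 0:(n_coeffs - 1)),
            paste0("ddmfcc", 0:(n_coeffs - 1)))
  c(paste0(base, "_mean"), paste0(base, "_sd"))
}

#' Feature schema
#'
#' Fixed, ordered names of the per-recording feature vector produced by
#' [featurize()].
#'
#' @param n_coeffs Number of MFCC coefficients summarized.
#' @return Character vector of column names.
#' @export
feature_schema <- function(n_coeffs = 13) {
  c("zcr_mean", "zcr_sd", "centroid_mean", "centroid_sd",
    "bandwidth_mean", "bandwidth_sd", "flatness_mean", "flatness_sd",
    "contrast_mean", "contrast_sd",
    "f0_mean_hz", "f0_sd_hz",
    "jitter_pct", "shimmer_pct", "shimmer_db", "hnr_db",
    "f1_hz", "f2_hz", "f3_hz",
    mfcc_stat_names(n_coeffs))
}

#' Per-recording acoustic feature vector
#'
#' Aggregates the full voice-quality suite over one sustained-vowel
#' recording: framewise spectral descriptors (ZCR, centroid, bandwidth,
#' flatness, contrast) summarized by mean and standard deviation;
#' fundamental-frequency statistics; jitter, shimmer (percent and dB) and
#' HNR from extracted glottal cycles; median LPC formants F1-F3 over voiced
#' frames; and mean/sd of 13 MFCCs with their delta and delta-delta tracks.
#'
#' The schema is fixed (see [feature_schema()]): a fully unvoiced input
#' yields `NA` voice-quality fields but the same columns, and extraction is
#' deterministic.
#'
#' @param signal An [audio_signal()] of at least 0.5 s.
#' @param params STFT geometry for framewise features.
#' @param f0_range Pitch search range in Hz.
#' @param n_coeffs,n_mels,delta_width MFCC configuration.
#' @return One-row `data.frame` with the schema columns plus `label`;
#'   attribute `schema_version` records the schema revision.
#' @export
featurize <- function(signal, params = stft_params(signal$rate),
                      f0_range = c(75, 500),
                      n_coeffs = 13, n_mels = 40, delta_width = 2) {
  stopifnot(inherits(signal, "audio_signal"))
  if (duration(signal) < 0.5) {
    dv_stop("dysvoice_error_short_signal", "need at least 0.5 s of audio")
  }
  spec <- stft(signal, params)
  mags <- Mod(spec$values)
  frames <- frame_signal(signal$samples, params$frame_length, params$hop)
  zcr <- apply(frames, 2, zero_crossing_rate)
  desc <- apply(mags, 2, function(m) {
    d <- spectral_descriptors(m, spec$freqs)
    c(d$centroid, d$bandwidth, d$flatness, d$contrast)
  })
  out <- list(
    zcr_mean = mean(zcr), zcr_sd = sd(zcr),
    centroid_mean = mean(desc[1, ], na.rm = TRUE),
    centroid_sd = sd(desc[1, ], na.rm = TRUE),
    bandwidth_mean = mean(desc[2, ], na.rm = TRUE),
    bandwidth_sd = sd(desc[2, ], na.rm = TRUE),
    flatness_mean = mean(desc[3, ], na.rm = TRUE),
    flatness_sd = sd(desc[3, ], na.rm = TRUE),
    contrast_mean = mean(desc[4, ], na.rm = TRUE),
    contrast_sd = sd(desc[4, ], na.rm = TRUE)
  )
  # voice-quality block: NA (schema preserved) when no stable voicing exists
  vq <- tryCatch({
    track <- track_f0(signal, range = f0_range)
    cycles <- extract_cycles(signal, track)
    f0v <- track$f0[track$voicing]
    list(f0_mean_hz = mean(f0v), f0_sd_hz = sd(f0v),
         jitter_pct = jitter_percent(cycles),
         shimmer_pct = shimmer_percent(cycles),
         shimmer_db = shimmer_db(cycles),
         hnr_db = hnr_db(signal, track, cycles),
         formants = voiced_formants(signal, track, params))
  }, dysvoice_error = function(e) {
    list(f0_mean_hz = NA_real_, f0_sd_hz = NA_real_, jitter_pct = NA_real_,
         shimmer_pct = NA_real_, shimmer_db = NA_real_, hnr_db = NA_real_,
         formants = c(F1 = NA_real_, F2 = NA_real_, F3 = NA_real_))
  })
  out <- c(out, vq[c("f0_mean_hz", "f0_sd_hz", "jitter_pct", "shimmer_pct",
                     "shimmer_db", "hnr_db")],
           list(f1_hz = vq$formants[["F1"]], f2_hz = vq$formants[["F2"]],
                f3_hz = vq$formants[["F3"]]))
  mf <- mfcc_stack(signal, params, n_coeffs, n_mels, delta_width)
  stacks <- rbind(mf$mfcc, mf$delta, mf$delta2)
  mstats <- c(rowMeans(stacks), apply(stacks, 1, sd))
  names(mstats) <- mfcc_stat_names(n_coeffs)
  row <- data.frame(c(out, as.list(mstats)), check.names = FALSE)
  row <- row[, feature_schema(n_coeffs)]
  row$label <- signal$label
  attr(row, "schema_version") <- feature_schema_version
  row
}

# Median formants over a subsample of voiced frames (30 ms windows).
voiced_formants <- function(signal, track, params) {
  vt <- track$times[track$voicing]
  if (!length(vt)) return(c(F1 = NA_real_, F2 = NA_real_, F3 = NA_real_))
  n_win <- round(0.030 * signal$rate)
  pick <- vt[seq(1, length(vt), length.out = min(15, length(vt)))]
  ests <- vapply(pick, function(tc) {
    c0 <- round(tc * signal$rate)
    lo <- max(1, c0 - n_win %/% 2)
    hi <- min(length(signal$samples), lo + n_win - 1)
    f <- tryCatch(formants_lpc(signal$samples[lo:hi], signal$rate),
                  dysvoice_error = function(e) NULL)
    if (is.null(f) || !f$reliable) rep(NA_real_, 3) else f$formants
  }, numeric(3))
  out <- apply(ests, 1, median, na.rm = TRUE)
  names(out) <- c("F1", "F2", "F3")
  out
}

#' Featurize a labeled corpus
#'
#' @param corpus A `labeled_corpus` from [make_corpus()], or a list of
#'   [audio_signal()] objects.
#' @param ... Passed to [featurize()].
#' @return A `data.frame`, one row per recording, schema columns + `label`.
#' @export
featurize_corpus <- function(corpus, ...) {
  signals <- if (inherits(corpus, "labeled_corpus")) corpus$signals else corpus
  rows <- lapply(signals, featurize, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schema_version") <- feature_schema_version
  out
}
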