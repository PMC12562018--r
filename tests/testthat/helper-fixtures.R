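# Shared fixtures, built once per test run and memoized (the 81-item corpus
# and its derived representations are used by several files).

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

corpus81 <- function() {
  get_fixture("corpus81", function() make_corpus(40, 41, seed = 11))
}

feats81 <- function() {
  get_fixture("feats81", function() featurize_corpus(corpus81()))
}

grids81 <- function() {
  get_fixture("grids81", function() corpus_mel_array(corpus81()))
}

# A clean, steady synthetic vowel reused across feature tests.
clean_vowel <- function() {
  get_fixture("clean_vowel", function() {
    synth_vowel(voice_profile(f0_mean = 200, f0_sd = 0, jitter_pct = 0,
                              shimmer_pct = 0, hnr_db = 60),
                rate = 8000, seed = 3)
  })
}

# Hand-built cycle sequence (no extraction flags): statistics evaluate the
# printed formulas verbatim.
manual_cycles <- function(periods_s, amplitudes = NULL) {
  if (is.null(amplitudes)) amplitudes <- rep(1, length(periods_s))
  structure(list(periods = periods_s, amplitudes = amplitudes,
                 runs = NULL, marks = NULL, rate = NA_real_),
            class = "pitch_cycles")
}

# Independent metric oracle: per-item counting and direct formula
# evaluation, written without reference to the package implementation.
oracle_metrics <- function(y, p) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) tp <- tp + 1
    if (y[i] == 0 && p[i] == 1) fp <- fp + 1
    if (y[i] == 0 && p[i] == 0) tn <- tn + 1
    if (y[i] == 1 && p[i] == 0) fn <- fn + 1
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y),
       precision = prec, recall = rec,
       specificity = div(tn, tn + fp),
       f1 = if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
            else 2 * prec * rec / (prec + rec),
       mcc = {
         den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
         if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
       })
}

# PCM16 WAV fixture written to a temp file.
write_temp_wav <- function(samples, rate) {
  path <- tempfile(fileext = ".wav")
  write_wav(audio_signal(samples, rate), path)
  path
}
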