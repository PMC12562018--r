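#' Pipeline configuration
#'
#' One declarative object driving the end-to-end workflow: data source
#' (built-in synthesizer or a directory of labeled WAVs), preprocessing,
#' feature/selection settings, the model, and the evaluation protocol.
#'
#' @param n_pd,n_hc Synthetic class sizes (ignored when `audio_dir` given).
#' @param seed Master seed for the whole run.
#' @param rate Analysis sampling rate in Hz.
#' @param duration Fixed segment length in seconds.
#' @param denoise Apply spectral gating before feature extraction.
#' @param model `"BiLSTM"`, `"CNN_LSTM"`, `"CNN_GRU"`, `"DNN"` (deep, mel
#'   grids) or `"SVM"`, `"GBOOST"`, `"LOGREG"` (classical, feature vectors).
#' @param epochs Training epochs for deep models (`NULL` = per-architecture
#'   default).
#' @param selection Feature selection for classical models: `"none"`,
#'   `"mi"` or `"rfe"`.
#' @param n_keep Features kept by selection.
#' @param protocol `"split"` (stratified 80-20) or `"kfold"`.
#' @param k Folds for `"kfold"`.
#' @param jitter_spread Corpus spread passed to [make_corpus()].
#' @param audio_dir Optional directory of labeled WAVs (subdirectories
#'   `PD/` and `HC/`).
#' @param out_dir Optional output directory for artifacts.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(n_pd = 40, n_hc = 41, seed = 1, rate = 8000,
                            duration = 3, denoise = FALSE, model = "BiLSTM",
                            epochs = NULL,
                            selection = c("none", "mi", "rfe"), n_keep = 20,
                            protocol = c("split", "kfold"), k = 10,
                            jitter_spread = 0.15,
                            audio_dir = NULL, out_dir = NULL) {
  model <- match.arg(model, c("BiLSTM", "CNN_LSTM", "CNN_GRU", "DNN",
                              "SVM", "GBOOST", "LOGREG"))
  if (!is.null(audio_dir) && !dir.exists(audio_dir)) {
    dv_stop("dysvoice_error_missing_file", "audio_dir %s not found", audio_dir)
  }
  structure(list(n_pd = n_pd, n_hc = n_hc, seed = seed, rate = rate,
                 duration = duration, denoise = denoise, model = model,
                 epochs = epochs, selection = match.arg(selection),
                 n_keep = n_keep, protocol = match.arg(protocol), k = k,
                 jitter_spread = jitter_spread,
                 audio_dir = audio_dir, out_dir = out_dir),
            class = "pipeline_config")
}

is_deep <- function(name) name %in% c("BiLSTM", "CNN_LSTM", "CNN_GRU", "DNN")

#' Run the full screening pipeline
#'
#' Orchestrates: synthesize-or-load -> (optional) denoise -> feature
#' extraction (mel grids for deep models, Table-style feature vectors for
#' classical ones) -> feature selection (classical path) -> training ->
#' evaluation. Every stage logs its parameters; a rerun with the same
#' configuration reproduces the report.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return An `eval_report` with attached `model` and, for deep models,
#'   training `history`. Artifacts (features.csv, selection.csv,
#'   report.json, run.json) are written when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  corpus <- if (is.null(config$audio_dir)) {
    say("[data] synthetic corpus: %d PD / %d HC, seed %d",
        config$n_pd, config$n_hc, config$seed)
    make_corpus(config$n_pd, config$n_hc, config$jitter_spread,
                seed = config$seed, rate = config$rate,
                duration = config$duration)
  } else {
    say("[data] loading WAVs from %s", config$audio_dir)
    load_audio_dir(config$audio_dir, config$rate, config$duration)
  }
  if (config$denoise) {
    say("[denoise] spectral gating (k=1.5, alpha=0.1, T=10)")
    corpus$signals <- lapply(corpus$signals, denoise)
  }
  y <- as.integer(corpus$manifest$label == "PD")
  deep <- is_deep(config$model)
  features <- NULL; sel <- NULL
  if (deep) {
    say("[features] %d log-mel grids (40 x 128)", length(corpus$signals))
    grids <- corpus_mel_array(corpus)
    x <- grids$x
  } else {
    say("[features] acoustic feature vectors (%d columns)",
        length(feature_schema()))
    features <- featurize_corpus(corpus)
    fm <- feature_matrix(features)
    x <- fm$x
    if (config$selection != "none") {
      sel <- if (config$selection == "mi") {
        s <- mutual_information_rank(fm)
        s$kept <- head(s$ranked$feature, config$n_keep)
        s
      } else rfe_select(fm, n_keep = config$n_keep)
      say("[select] %s kept %d features", toupper(config$selection),
          length(sel$kept))
      x <- x[, sel$kept, drop = FALSE]
    }
  }
  builder <- function(x_tr, y_tr) {
    if (deep) {
      spec <- build_model(config$model)
      train_model(spec, x_tr, y_tr,
                  train_config(epochs = config$epochs, seed = config$seed))
    } else {
      fit_classical(config$model, structure(list(x = x_tr, y = y_tr),
                                            class = "feature_matrix"),
                    seed = config$seed)
    }
  }
  say("[train] %s, protocol %s", config$model, config$protocol)
  if (config$protocol == "kfold") {
    report <- kfold_cv(builder, x, y, k = config$k, seed = config$seed)
  } else {
    te <- with_seed(config$seed, stratified_split(y, 0.2))
    tr <- setdiff(seq_along(y), te)
    take <- function(idx) {
      if (deep) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
    }
    model <- builder(take(tr), y[tr])
    report <- evaluate_model(model, take(te), y[te])
    report$model <- model
    report$test_idx <- te
    if (deep) report$history <- model$history
  }
  say("[evaluate] accuracy %.3f, AUC %s", report$metrics$accuracy,
      ifelse(is.na(report$auc), "NA", sprintf("%.3f", report$auc)))
  if (!is.null(config$out_dir)) {
    write_artifacts(config, corpus, features, sel, report)
  }
  report
}

write_artifacts <- function(config, corpus, features, sel, report) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, null = "null")
  write.csv(corpus$manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  if (!is.null(features)) {
    write.csv(features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
  }
  if (!is.null(sel)) {
    write.csv(sel$ranked, file.path(config$out_dir, "selection.csv"),
              row.names = FALSE)
  }
  flat <- list(metrics = report$metrics[c("accuracy", "precision", "recall",
                                          "specificity", "f1", "mcc")],
               auc = report$auc)
  if (!is.null(report$folds)) flat$folds <- report$folds
  jsonlite::write_json(flat, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

# Directory adapter: expects <dir>/PD/*.wav and <dir>/HC/*.wav.
load_audio_dir <- function(dir, rate, duration) {
  signals <- list(); labels <- character(0); files <- character(0)
  for (lab in c("PD", "HC")) {
    fs <- list.files(file.path(dir, lab), pattern = "\\.wav$",
                     full.names = TRUE)
    for (f in fs) {
      sig <- load_wav(f, target_rate = rate)
      sig <- segment_fixed(sig, segment_policy(duration))
      sig$label <- lab
      signals[[length(signals) + 1]] <- sig
      labels <- c(labels, lab); files <- c(files, f)
    }
  }
  if (!length(signals)) {
    dv_stop("dysvoice_error_missing_file", "no WAV files under %s", dir)
  }
  structure(list(signals = signals,
                 manifest = data.frame(id = seq_along(files), label = labels,
                                       file = files)),
            class = "labeled_corpus")
}
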