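# Base-graphics displays for the main result objects.

#' @export
plot.audio_signal <- function(x, ...) {
  tt <- (seq_along(x$samples) - 1) / x$rate
  plot(tt, x$samples, type = "l", xlab = "time (s)", ylab = "amplitude",
       main = sprintf("waveform (%s)", x$label), ...)
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, db_floor = -80, ...) {
  db <- 20 * log10(pmax(Mod(x$values), 1e-12))
  db <- pmax(db - max(db), db_floor)
  tt <- (seq_len(ncol(db)) - 1) * x$params$hop / x$rate
  image(tt, x$freqs, t(db), xlab = "time (s)", ylab = "frequency (Hz)",
        main = "spectrogram (dB)", useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.mel_spectrogram <- function(x, ...) {
  image(seq_len(x$n_frames), seq_len(x$n_mels), t(x$values),
        xlab = "frame", ylab = "mel band", main = "log-mel spectrogram (dB)",
        useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.pitch_track <- function(x, ...) {
  plot(x$times, ifelse(x$voicing, x$f0, NA), type = "p", pch = 16, cex = 0.5,
       xlab = "time (s)", ylab = "F0 (Hz)", ylim = x$search_range,
       main = "pitch track", ...)
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  if (!is.null(x$history)) {
    h <- x$history
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
    plot(h$epoch, h$acc, type = "l", ylim = c(0, 1), xlab = "epoch",
         ylab = "accuracy", main = "training history")
    graphics::lines(h$epoch, h$val_acc, lty = 2)
    plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
         main = "loss")
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  } else if (!is.null(x$roc)) {
    plot(structure(list(auc = x$auc, roc = x$roc), class = "roc_result"), ...)
  }
  invisible(x)
}
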