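#' Assemble a feature matrix for selection and classical models
#'
#' @param features Data frame from [featurize_corpus()] (schema columns +
#'   `label`).
#' @param impute How to handle missing values: `"median"` (per-column
#'   median imputation) or `"error"`.
#' @return A `feature_matrix`: numeric matrix `x` (named columns) and a
#'   binary `y` (1 = PD).
#' @export
feature_matrix <- function(features, impute = c("median", "error")) {
  impute <- match.arg(impute)
  stopifnot(is.data.frame(features), "label" %in% names(features))
  y <- as.integer(features$label == "PD")
  x <- as.matrix(features[, setdiff(names(features), "label"), drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    if (impute == "error") {
      dv_stop("dysvoice_error_missing_values", "feature matrix contains NA")
    }
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- median(x[, j], na.rm = TRUE)
    }
    x[is.na(x)] <- 0   # all-NA column
  }
  structure(list(x = x, y = y), class = "feature_matrix")
}

#' Rank features by mutual information with the class label
#'
#' Each column is discretized by equal-frequency binning and the mutual
#' information with the binary label is computed in bits,
#' `MI = sum p(x, y) log2(p(x, y) / (p(x) p(y)))`. Features are returned in
#' descending MI order, ties broken by schema order.
#'
#' @param data A [feature_matrix()] (or data frame accepted by it).
#' @param n_bins Number of equal-frequency bins (default 8).
#' @return A `selection_result`: `ranked` data.frame (feature, score) and
#'   `method = "MI"`.
#' @export
mutual_information_rank <- function(data, n_bins = 8) {
  data <- as_feature_matrix(data)
  if (length(unique(data$y)) < 2) {
    dv_stop("dysvoice_error_one_class", "need both classes present")
  }
  scores <- apply(data$x, 2, function(col) {
    mutual_information(equal_freq_bin(col, n_bins), data$y)
  })
  ord <- order(-scores, seq_along(scores))
  structure(list(
    ranked = data.frame(feature = colnames(data$x)[ord],
                        score = as.numeric(scores[ord])),
    kept = colnames(data$x)[ord],
    method = "MI"
  ), class = "selection_result")
}

equal_freq_bin <- function(x, n_bins) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
}

mutual_information <- function(xb, y) {
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (ii in seq_along(px)) for (jj in seq_along(py)) {
    if (p[ii, jj] > 0) {
      mi <- mi + p[ii, jj] * log2(p[ii, jj] / (px[ii] * py[jj]))
    }
  }
  max(0, as.numeric(mi))
}

#' Recursive feature elimination
#'
#' Repeatedly fits an L2-regularized linear classifier (ridge logistic
#' regression on standardized inputs) and drops the `step` columns with the
#' smallest absolute weights until `n_keep` remain. The full elimination
#' order is recorded; for `step = 1` the kept set at any size is nested in
#' the kept set one larger.
#'
#' @param data A [feature_matrix()] (or data frame accepted by it).
#' @param n_keep Number of features to retain (default 20).
#' @param step Columns dropped per iteration (default 1).
#' @param lambda Ridge penalty of the base scorer.
#' @return A `selection_result` with `kept`, the `elimination_order`
#'   (first-dropped first) and `method = "RFE"`.
#' @export
rfe_select <- function(data, n_keep = 20, step = 1, lambda = 0.1) {
  data <- as_feature_matrix(data)
  p <- ncol(data$x)
  if (n_keep >= p) {
    dv_stop("dysvoice_error_bad_params",
            "n_keep (%d) must be below the column count (%d)", n_keep, p)
  }
  remaining <- colnames(data$x)
  eliminated <- character(0)
  while (length(remaining) > n_keep) {
    w <- ridge_weights(data$x[, remaining, drop = FALSE], data$y, lambda)
    k <- min(step, length(remaining) - n_keep)
    drop_idx <- order(abs(w))[seq_len(k)]
    eliminated <- c(eliminated, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  w <- ridge_weights(data$x[, remaining, drop = FALSE], data$y, lambda)
  ranked <- data.frame(feature = c(remaining[order(-abs(w))], rev(eliminated)),
                       score = c(sort(abs(w), decreasing = TRUE),
                                 -seq_along(eliminated)))
  structure(list(ranked = ranked, kept = remaining,
                 elimination_order = eliminated, method = "RFE"),
            class = "selection_result")
}

# Standardized ridge-logistic weights via glmnet (alpha = 0).
ridge_weights <- function(x, y, lambda) {
  if (ncol(x) == 1) {
    # glmnet needs >= 2 columns; fall back to closed-form ridge on +-1 labels
    xs <- scale(x)
    xs[is.na(xs)] <- 0
    return(as.numeric(crossprod(xs, 2 * y - 1) / (nrow(x) + lambda)))
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  w <- as.numeric(coef(fit))[-1]
  # report on the standardized scale so weights are comparable
  sds <- apply(x, 2, sd)
  w * ifelse(sds > 0, sds, 0)
}

as_feature_matrix <- function(data) {
  if (inherits(data, "feature_matrix")) data else feature_matrix(data)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, %d features kept\n",
              x$method, length(x$kept)))
  print(head(x$ranked, 10))
  invisible(x)
}
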