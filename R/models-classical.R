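#' Fit a classical baseline with grid-search cross-validation
#'
#' Trains one of the three feature-vector baselines with stratified
#' grid-search CV on the training data only: RBF-kernel SVM (`e1071`),
#' gradient-boosted trees (`xgboost`; the prediction is the additive sum of
#' its per-tree outputs) or L2-regularized logistic regression (`glmnet`,
#' gridded over the regularization strength). Inputs are standardized with
#' training-set statistics.
#'
#' @param kind `"SVM"`, `"GBOOST"` or `"LOGREG"`.
#' @param data A [feature_matrix()] (or a featurized data frame).
#' @param hyper_grid Optional data.frame of hyperparameter combinations
#'   overriding the built-in grid.
#' @param cv_folds Number of stratified CV folds for the grid search.
#' @param seed Integer seed (fold assignment and stochastic fitters).
#' @return A `dysvoice_classical` model with the chosen hyperparameters,
#'   the CV table, and a [predict_proba()] method.
#' @export
fit_classical <- function(kind, data, hyper_grid = NULL, cv_folds = 5,
                          seed = 1) {
  kind <- match.arg(kind, c("SVM", "GBOOST", "LOGREG"))
  data <- as_feature_matrix(data)
  if (length(unique(data$y)) < 2) {
    dv_stop("dysvoice_error_one_class", "need both classes to fit")
  }
  ctr <- colMeans(data$x)
  scl <- apply(data$x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(data$x, ctr, scl)
  grid <- if (is.null(hyper_grid)) default_grid(kind, ncol(xs)) else hyper_grid
  if (!nrow(grid)) dv_stop("dysvoice_error_bad_params", "empty hyper grid")
  cv_folds <- max(2L, min(cv_folds, min(table(data$y))))
  folds <- with_seed(seed, stratified_folds(data$y, cv_folds))
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      if (all(tr) || length(unique(data$y[tr])) < 2) return(NA_real_)
      # small-sample inner folds trip glmnet's class-size advisories
      fit <- suppressWarnings(fit_one(kind, xs[tr, , drop = FALSE],
                                      data$y[tr], grid[g, , drop = FALSE],
                                      seed))
      p <- predict_one(kind, fit, xs[!tr, , drop = FALSE])
      mean((p >= 0.5) == data$y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_acc)
  if (!length(best)) best <- 1L
  fit <- fit_one(kind, xs, data$y, grid[best, , drop = FALSE], seed)
  structure(list(kind = kind, fit = fit, center = ctr, scale = scl,
                 best = grid[best, , drop = FALSE],
                 cv = cbind(grid, cv_acc = cv_acc),
                 features = colnames(data$x)),
            class = c("dysvoice_classical", "dysvoice_model"))
}

default_grid <- function(kind, p) {
  switch(kind,
    SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.5, 1, 2) / p),
    GBOOST = expand.grid(max_depth = c(2, 3), eta = c(0.1, 0.3),
                         nrounds = 50),
    LOGREG = data.frame(lambda = c(0.001, 0.01, 0.1, 1)))
}

fit_one <- function(kind, x, y, hp, seed) {
  with_seed(seed, switch(kind,
    SVM = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = hp$cost, gamma = hp$gamma, probability = TRUE),
    GBOOST = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$nrounds, verbose = 0),
    LOGREG = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = hp$lambda)))
}

predict_one <- function(kind, fit, x) {
  switch(kind,
    SVM = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    GBOOST = as.numeric(predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    LOGREG = as.numeric(predict(fit, x, type = "response")))
}

#' @export
predict_proba.dysvoice_classical <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)[, model$features, drop = FALSE]
  xs <- scale(x, model$center, model$scale)
  predict_one(model$kind, model$fit, xs)
}

# Stratified fold labels 1..k (round-robin within shuffled classes).
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}
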