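test_that("confusion counting partitions items and swaps symmetrically", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(unclass(confusion(y, y))[c("tp", "tn", "fp", "fn")],
               list(tp = 5, tn = 5, fp = 0, fn = 0))
  allpos <- confusion(y, rep(1, 10))
  expect_equal(c(allpos$tp, allpos$fp, allpos$tn, allpos$fn), c(5, 5, 0, 0))
  a <- confusion(y, c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0))
  b <- confusion(y, 1 - c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0))
  expect_equal(a$tp, b$fn); expect_equal(a$tn, b$fp)
  expect_error(confusion(y, y[-1]), class = "dysvoice_error_length_mismatch")
  expect_error(confusion(y, y * 2), class = "dysvoice_error_not_binary")
})

test_that("metric formulas agree exactly with the counting oracle", {
  # hand-evaluated case
  m <- metrics(structure(list(tp = 45, fn = 5, tn = 40, fp = 10),
                         class = "confusion_counts"))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 45 / 55)
  expect_equal(m$recall, 0.9)
  expect_equal(m$specificity, 0.8)
  # perfect-classifier limit
  mp <- metrics(structure(list(tp = 5, tn = 5, fp = 0, fn = 0),
                          class = "confusion_counts"))
  expect_equal(c(mp$accuracy, mp$f1, mp$mcc), c(1, 1, 1))
  # degenerate denominator (no actual negatives) is flagged, never a
  # silent zero; with actual negatives present specificity = 0 is defined
  md <- metrics(structure(list(tp = 5, fp = 0, tn = 0, fn = 0),
                          class = "confusion_counts"))
  expect_true(is.na(md$specificity))
  expect_true("specificity" %in% md$undefined)
  m0 <- metrics(structure(list(tp = 5, fp = 5, tn = 0, fn = 0),
                          class = "confusion_counts"))
  expect_equal(m0$specificity, 0)
  # randomized agreement with the oracle at n <= 12
  set.seed(40)
  for (rep_i in 1:120) {
    n <- sample(1:12, 1)
    y <- rbinom(n, 1, 0.5)
    p <- rbinom(n, 1, 0.5)
    got <- metrics(confusion(y, p))
    want <- oracle_metrics(y, p)
    for (f in c("accuracy", "precision", "recall", "specificity",
                "f1", "mcc")) {
      expect_identical(is.na(got[[f]]), is.na(want[[f]]))
      if (!is.na(want[[f]])) expect_equal(got[[f]], want[[f]])
    }
  }
})

test_that("MCC is symmetric under a simultaneous class swap", {
  set.seed(41)
  y <- rbinom(30, 1, 0.4); p <- rbinom(30, 1, 0.6)
  m1 <- metrics(confusion(y, p))
  m2 <- metrics(confusion(1 - y, 1 - p))
  expect_equal(m1$mcc, m2$mcc)
})

test_that("ROC/AUC honors tie and reversal conventions", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(y, c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(y, rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.2, 0.1))$auc, 0)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)),
               class = "dysvoice_error_one_class")
})

test_that("AUC is invariant under monotone transforms and matches pROC", {
  set.seed(42)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60) + y
  a1 <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(s))$auc, a1)
  expect_equal(roc_auc(y, qlogis(plogis(s)))$auc, a1, tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-12)
  # ties against the Mann-Whitney convention, cross-checked with wilcox
  st <- round(s)                                  # heavy ties
  w <- wilcox.test(st[y == 1], st[y == 0], exact = FALSE, correct = FALSE)
  auc_mw <- w$statistic / (sum(y == 1) * sum(y == 0))
  expect_equal(roc_auc(y, st)$auc, as.numeric(auc_mw), tolerance = 1e-12)
})

test_that("stratified k-fold CV partitions items and is reproducible", {
  set.seed(43)
  x <- matrix(rnorm(24 * 3), 24)
  colnames(x) <- c("a", "b", "c")
  y <- rep(c(0L, 1L), each = 12)
  x[y == 1, 1] <- x[y == 1, 1] + 4
  builder <- function(xt, yt) {
    fit_classical("LOGREG", structure(list(x = xt, y = yt),
                                      class = "feature_matrix"),
                  hyper_grid = data.frame(lambda = 0.1), seed = 1)
  }
  r <- kfold_cv(builder, x, y, k = 4, seed = 9)
  expect_equal(nrow(r$folds), 4)
  expect_equal(sort(unique(r$fold_assignment)), 1:4)
  expect_length(r$scores, 24)
  expect_gte(r$metrics$accuracy, 0.9)
  r2 <- kfold_cv(builder, x, y, k = 4, seed = 9)
  expect_identical(r$fold_assignment, r2$fold_assignment)
  expect_equal(r$scores, r2$scores)
  # leave-one-out on the smallest class: every fold holds both classes
  r3 <- kfold_cv(builder, x, y, k = 12, seed = 2)
  expect_equal(as.numeric(table(r3$fold_assignment)), rep(2, 12))
  expect_error(kfold_cv(builder, x, y, k = 13, seed = 1),
               class = "dysvoice_error_bad_params")
})
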