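make_fm <- function(x, y) {
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  structure(list(x = x, y = y), class = "feature_matrix")
}

test_that("mutual information is 1 bit for a perfectly dependent feature", {
  set.seed(15)
  y <- rep(c(0L, 1L), each = 250)
  x <- cbind(as.numeric(y), rnorm(500))
  res <- mutual_information_rank(make_fm(x, y))
  expect_equal(res$ranked$score[res$ranked$feature == "f01"], 1,
               tolerance = 1e-10)
  expect_equal(res$ranked$feature[1], "f01")
})

test_that("independent features score near zero and duplicates tie", {
  set.seed(16)
  y <- rep(c(0L, 1L), each = 250)
  noise <- rnorm(500)
  x <- cbind(noise, noise, rnorm(500))
  res <- mutual_information_rank(make_fm(x, y))
  scores <- setNames(res$ranked$score, res$ranked$feature)
  expect_lt(scores[["f03"]], 0.05)
  expect_equal(scores[["f01"]], scores[["f02"]])
  expect_error(mutual_information_rank(make_fm(x, rep(1L, 500))),
               class = "dysvoice_error_one_class")
})

test_that("mutual information respects its entropy bounds", {
  set.seed(17)
  y <- rbinom(300, 1, 0.4)
  h_y <- -sum(table(y) / 300 * log2(table(y) / 300))
  for (i in 1:10) {
    x <- matrix(rnorm(300) + y * runif(1, 0, 3), ncol = 1)
    res <- mutual_information_rank(make_fm(x, y))
    expect_gte(res$ranked$score[1], 0)
    expect_lte(res$ranked$score[1], log2(8) + 1e-9)
    expect_lte(res$ranked$score[1], h_y + 1e-9)
  }
})

test_that("RFE keeps a dominant predictor and eliminates nested sets", {
  set.seed(18)
  y <- rep(c(0L, 1L), each = 60)
  x <- cbind(as.numeric(y) + rnorm(120, sd = 0.05),
             matrix(rnorm(120 * 9), 120))
  fm <- make_fm(x, y)
  for (nk in c(1, 3, 6)) {
    expect_true("f01" %in% rfe_select(fm, n_keep = nk)$kept)
  }
  r1 <- rfe_select(fm, n_keep = 9)
  expect_length(r1$elimination_order, 1)
  # determinism
  expect_identical(rfe_select(fm, 4)$elimination_order,
                   rfe_select(fm, 4)$elimination_order)
  # nested keeps for step = 1 (from one elimination ordering)
  r <- rfe_select(fm, n_keep = 2)
  order_full <- c(r$elimination_order, rev(setdiff(colnames(x),
                                                   r$elimination_order)))
  kept_at <- function(k) tail(setdiff(colnames(x), head(r$elimination_order,
                                                        ncol(x) - k)), k)
  expect_true(all(kept_at(3) %in% kept_at(4)))
  expect_error(rfe_select(fm, n_keep = 10),
               class = "dysvoice_error_bad_params")
})

test_that("feature_matrix imputes missing cells by column medians", {
  f <- data.frame(a = c(1, NA, 3), b = c(2, 2, 2), label = c("PD", "HC", "PD"))
  fm <- feature_matrix(f)
  expect_equal(unname(fm$x[2, "a"]), 2)
  expect_equal(fm$y, c(1L, 0L, 1L))
  expect_error(feature_matrix(f, impute = "error"),
               class = "dysvoice_error_missing_values")
})
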