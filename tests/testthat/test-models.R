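test_that("built specs mirror the published layer stacks", {
  dnn <- build_model("DNN")
  kinds <- vapply(dnn$layers, `[[`, "", "kind")
  expect_equal(kinds, c("flatten", "dense", "dropout", "dense", "dropout",
                        "dense", "dense"))
  units <- vapply(dnn$layers[kinds == "dense"], `[[`, 1, "units")
  expect_equal(units, c(256, 128, 64, 1))
  for (arch in c("BiLSTM", "CNN_LSTM", "CNN_GRU", "DNN")) {
    spec <- build_model(arch)
    last <- spec$layers[[length(spec$layers)]]
    expect_equal(last$kind, "dense")
    expect_equal(last$units, 1)
    expect_equal(last$activation, "sigmoid")
  }
  bi <- build_model("BiLSTM")
  expect_equal(bi$layers[[3]]$kernel, c(2, 3))
  expect_true(bi$layers[[6]]$bidirectional)
  expect_error(build_model("Transformer"))
})

test_that("parameter counts match layer-by-layer arithmetic", {
  # DNN on 40 x 128: 5120*256+256 + 256*128+128 + 128*64+64 + 64*1+1
  expect_equal(count_params(build_model("DNN")),
               5120 * 256 + 256 + 256 * 128 + 128 + 128 * 64 + 64 + 64 + 1)
  # bidirectional layers double their stated width on output
  net <- dysvoice:::nn_init(build_model("BiLSTM"), seed = 1)
  rec2 <- net$descs[[7]]
  expect_equal(rec2$kind, "recurrent")
  expect_equal(rec2$input_dim, 128)          # 64 fwd + 64 bwd
  expect_equal(rec2$in_shape, c(40, 128))
})

test_that("backpropagation matches numerical gradients", {
  set.seed(2)
  spec <- structure(list(name = "tiny", layers = list(
    list(kind = "conv2d", filters = 2, kernel = c(3, 3), activation = "relu"),
    list(kind = "maxpool"),
    list(kind = "reshape_seq", timesteps = 4),
    list(kind = "recurrent", cell = "lstm", units = 3,
         return_sequences = TRUE, bidirectional = TRUE),
    list(kind = "recurrent", cell = "gru", units = 2,
         return_sequences = FALSE, bidirectional = FALSE),
    list(kind = "dense", units = 1, activation = "sigmoid")),
    input_shape = c(4, 6)), class = "model_spec")
  net <- dysvoice:::nn_init(spec, seed = 3)
  x <- array(rnorm(2 * 4 * 6), c(2, 4, 6, 1))
  y <- c(1, 0)
  loss_of <- function(nn) {
    dysvoice:::bce_loss(as.numeric(dysvoice:::nn_forward(nn, x, FALSE)$out), y)
  }
  fw <- dysvoice:::nn_forward(net, x, FALSE)
  p <- as.numeric(fw$out)
  grads <- dysvoice:::nn_backward(net, fw$caches,
                                  matrix((p - y) / 2, ncol = 1))
  eps <- 1e-6
  flat_paths <- function(pp, path = c()) {
    if (is.list(pp)) {
      do.call(c, lapply(seq_along(pp), function(k) {
        flat_paths(pp[[k]], c(path, k))
      }))
    } else list(path)
  }
  worst <- 0
  for (li in seq_along(net$params)) {
    pr <- net$params[[li]]
    if (is.null(pr)) next
    for (path in flat_paths(pr)) {
      gP <- grads[[li]]; pP <- pr
      for (k in path) { gP <- gP[[k]]; pP <- pP[[k]] }
      for (ii in unique(c(1, length(pP)))) {
        net2 <- net
        q <- net2$params[[li]]
        if (length(path) == 1) q[[path[1]]][ii] <- q[[path[1]]][ii] + eps
        else q[[path[1]]][[path[2]]][ii] <- q[[path[1]]][[path[2]]][ii] + eps
        net2$params[[li]] <- q
        num <- (loss_of(net2) - loss_of(net)) / eps
        worst <- max(worst, abs(num - gP[ii]) /
                       max(1e-4, abs(num) + abs(gP[ii])))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("deep training overfits separable grids and is reproducible", {
  set.seed(30)
  y <- rep(c(0, 1), each = 10)
  x <- array(rnorm(20 * 40 * 128, sd = 0.5), c(20, 40, 128))
  x[y == 1, , 1:32] <- x[y == 1, , 1:32] + 1
  m <- train_model(build_model("DNN"), x, y,
                   train_config(epochs = 30, seed = 4))
  h <- m$history
  expect_gte(tail(h$acc, 1), 0.95)
  expect_true(all(is.finite(h$loss)))
  expect_lt(min(h$loss), h$loss[1])
  # deterministic given the seed
  m2 <- train_model(build_model("DNN"), x, y,
                    train_config(epochs = 30, seed = 4))
  expect_lt(abs(tail(h$loss, 1) - tail(m2$history$loss, 1)), 1e-6)
  # probabilities lie in (0,1) and duplicates agree
  p <- predict_proba(m, x[c(1, 1, 5), , , drop = FALSE])
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[1], p[2])
  expect_error(train_model(build_model("DNN"), x, rep(1, 20)),
               class = "dysvoice_error_one_class")
})

test_that("stratified splits preserve the class ratio within one item", {
  set.seed(31)
  y <- c(rep(0, 31), rep(1, 50))
  idx <- dysvoice:::stratified_split(y, 0.2)
  expect_equal(sum(y[idx] == 0), round(31 * 0.2))
  expect_equal(sum(y[idx] == 1), round(50 * 0.2))
})

test_that("the boosted model is the additive sum of its trees", {
  set.seed(32)
  x <- matrix(rnorm(60 * 5), 60)
  colnames(x) <- paste0("f", 1:5)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(60, sd = 0.3) > 0)
  fm <- structure(list(x = x, y = y), class = "feature_matrix")
  mdl <- fit_classical("GBOOST", fm,
                       hyper_grid = data.frame(max_depth = 2, eta = 0.3,
                                               nrounds = 8),
                       seed = 2)
  xs <- scale(x, mdl$center, mdl$scale)
  dmat <- xgboost::xgb.DMatrix(xs, nthread = 1)
  marg <- predict(mdl$fit, dmat, outputmargin = TRUE)
  leaves <- predict(mdl$fit, dmat, predleaf = TRUE)
  dt <- xgboost::xgb.model.dt.tree(model = mdl$fit)
  tree_sum <- vapply(seq_len(nrow(xs)), function(i) {
    sum(vapply(seq_len(ncol(leaves)), function(k) {
      dt$Gain[dt$Tree == k - 1 & dt$Node == leaves[i, k]]
    }, numeric(1)))
  }, numeric(1))
  offset <- marg - tree_sum
  expect_lt(diff(range(offset)), 1e-5)              # constant intercept only
  expect_equal(offset[1], qlogis(mean(y)), tolerance = 1e-5)
})

test_that("logistic probabilities follow the sigmoid of the linear score", {
  set.seed(33)
  x <- matrix(rnorm(80 * 3), 80)
  colnames(x) <- c("a", "b", "c")
  y <- as.integer(x[, 1] - x[, 2] > 0)
  fm <- structure(list(x = x, y = y), class = "feature_matrix")
  mdl <- fit_classical("LOGREG", fm,
                       hyper_grid = data.frame(lambda = 0.05), seed = 3)
  expect_equal(as.numeric(mdl$best$lambda), 0.05)   # single grid point wins
  p <- predict_proba(mdl, x)
  xs <- scale(x, mdl$center, mdl$scale)
  beta <- as.numeric(coef(mdl$fit))
  z <- beta[1] + xs %*% beta[-1]
  expect_equal(p, as.numeric(1 / (1 + exp(-z))), tolerance = 1e-10)
  expect_gte(mean((p >= 0.5) == y), 0.95)           # separable construction
  expect_equal(predict_proba(mdl, x[c(2, 2), ])[1],
               predict_proba(mdl, x[c(2, 2), ])[2])
})

test_that("SVM baseline fits and scores separable data", {
  set.seed(34)
  x <- matrix(rnorm(60 * 2), 60)
  colnames(x) <- c("u", "v")
  y <- as.integer(x[, 1] > 0)
  fm <- structure(list(x = x, y = y), class = "feature_matrix")
  mdl <- fit_classical("SVM", fm, seed = 4)
  expect_gte(mean((predict_proba(mdl, x) >= 0.5) == y), 0.9)
  expect_error(fit_classical("SVM",
                             structure(list(x = x, y = rep(0L, 60)),
                                       class = "feature_matrix")),
               class = "dysvoice_error_one_class")
})
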