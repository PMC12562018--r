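#' Deep model architectures
#'
#' Declarative layer stacks for the four deep classifiers operating on
#' log-mel grids (40 timesteps x 128 mel bands):
#'
#' * `CNN_LSTM`: Conv2D(32, 3x3, ReLU, same) -> MaxPool(2x2) ->
#'   Conv2D(64, 3x3, ReLU, same) -> MaxPool(2x2) -> Flatten ->
#'   Reshape(40 timesteps) -> LSTM(64, return_sequences) -> LSTM(32) ->
#'   Dense(64, ReLU) + Dropout(0.5) -> Dense(1, sigmoid)
#' * `CNN_GRU`: as above with a 2x3 first kernel and GRU recurrence
#' * `BiLSTM`: as CNN_LSTM with a 2x3 second kernel and bidirectional LSTMs
#'   (concatenated forward/backward states double the output width)
#' * `DNN`: Flatten -> Dense(256, ReLU) + Dropout(0.5) ->
#'   Dense(128, ReLU) + Dropout(0.5) -> Dense(64, ReLU) -> Dense(1, sigmoid)
#'
#' The flatten-reshape pair maps the pooled 10 x 32 x 64 grid onto 40
#' timesteps of 512 features (time-major: timesteps follow the pooled time
#' axis). Every stack ends in a single sigmoid unit.
#'
#' @param name One of `"BiLSTM"`, `"CNN_LSTM"`, `"CNN_GRU"`, `"DNN"`.
#' @param input_shape Grid shape `c(timesteps, mel_bands)`, default
#'   `c(40, 128)`.
#' @return A `model_spec` (name, layer descriptors, input shape).
#' @export
build_model <- function(name, input_shape = c(40, 128)) {
  name <- match.arg(name, c("BiLSTM", "CNN_LSTM", "CNN_GRU", "DNN"))
  conv_stack <- function(k1, k2, cell, bidir) {
    list(
      list(kind = "conv2d", filters = 32, kernel = k1, activation = "relu"),
      list(kind = "maxpool"),
      list(kind = "conv2d", filters = 64, kernel = k2, activation = "relu"),
      list(kind = "maxpool"),
      list(kind = "reshape_seq", timesteps = input_shape[1]),
      list(kind = "recurrent", cell = cell, units = 64,
           return_sequences = TRUE, bidirectional = bidir),
      list(kind = "recurrent", cell = cell, units = 32,
           return_sequences = FALSE, bidirectional = bidir),
      list(kind = "dense", units = 64, activation = "relu"),
      list(kind = "dropout", rate = 0.5),
      list(kind = "dense", units = 1, activation = "sigmoid")
    )
  }
  layers <- switch(name,
    CNN_LSTM = conv_stack(c(3, 3), c(3, 3), "lstm", FALSE),
    CNN_GRU = conv_stack(c(2, 3), c(3, 3), "gru", FALSE),
    BiLSTM = conv_stack(c(3, 3), c(2, 3), "lstm", TRUE),
    DNN = list(
      list(kind = "flatten"),
      list(kind = "dense", units = 256, activation = "relu"),
      list(kind = "dropout", rate = 0.5),
      list(kind = "dense", units = 128, activation = "relu"),
      list(kind = "dropout", rate = 0.5),
      list(kind = "dense", units = 64, activation = "relu"),
      list(kind = "dense", units = 1, activation = "sigmoid")
    ))
  structure(list(name = name, layers = layers, input_shape = input_shape),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, input %s\n", x$name,
              paste(x$input_shape, collapse = " x ")))
  for (l in x$layers) {
    cat("  -", l$kind,
        if (!is.null(l$units)) l$units else if (!is.null(l$filters))
          paste0(l$filters, " @", paste(l$kernel, collapse = "x")) else "",
        "\n")
  }
  invisible(x)
}

# Initialize parameters and record the shape flowing into each layer.
nn_init <- function(spec, seed = 1) {
  with_seed(seed, {
    shape <- c(spec$input_shape, 1)           # (H, W, C)
    params <- vector("list", length(spec$layers))
    descs <- spec$layers
    for (i in seq_along(descs)) {
      d <- descs[[i]]
      descs[[i]]$in_shape <- shape
      if (d$kind == "conv2d") {
        n_in <- prod(d$kernel) * shape[3]
        W <- glorot_mat(n_in, d$filters)
        attr(W, "kh") <- d$kernel[1]; attr(W, "kw") <- d$kernel[2]
        params[[i]] <- list(W = W, b = numeric(d$filters))
        shape <- c(shape[1], shape[2], d$filters)
      } else if (d$kind == "maxpool") {
        shape <- c(shape[1] %/% 2, shape[2] %/% 2, shape[3])
      } else if (d$kind == "flatten") {
        shape <- prod(shape)
      } else if (d$kind == "reshape_seq") {
        shape <- c(d$timesteps, prod(shape) / d$timesteps)
      } else if (d$kind == "recurrent") {
        init_fn <- if (d$cell == "lstm") lstm_cell_init else gru_cell_init
        pr <- list(fwd = init_fn(shape[2], d$units))
        if (d$bidirectional) pr$bwd <- init_fn(shape[2], d$units)
        params[[i]] <- pr
        descs[[i]]$input_dim <- shape[2]
        width <- d$units * (1 + d$bidirectional)
        shape <- if (d$return_sequences) c(shape[1], width) else width
      } else if (d$kind == "dense") {
        params[[i]] <- list(W = glorot_mat(shape, d$units),
                            b = numeric(d$units))
        shape <- d$units
      }
    }
    list(descs = descs, params = params, out_shape = shape)
  })
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$descs))
  for (i in seq_along(net$descs)) {
    d <- net$descs[[i]]
    p <- net$params[[i]]
    r <- switch(d$kind,
      conv2d = conv2d_forward(x, p$W, p$b, d$activation),
      maxpool = maxpool_forward(x),
      flatten = flatten_forward(x),
      reshape_seq = reshape_seq_forward(x, d$timesteps),
      recurrent = recurrent_forward(x, p, d),
      dense = dense_forward(x, p$W, p$b, d$activation),
      dropout = dropout_forward(x, d$rate, training))
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# dy at entry is the gradient at the sigmoid *pre-activation* of the final
# dense layer (BCE + sigmoid combined for stability).
nn_backward <- function(net, caches, dy) {
  n <- length(net$descs)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    d <- net$descs[[i]]
    p <- net$params[[i]]
    if (d$kind == "conv2d") {
      r <- conv2d_backward(dy, p$W, caches[[i]], d$activation)
      dy <- r$grad_in; grads[[i]] <- r$grads
    } else if (d$kind == "maxpool") {
      dy <- maxpool_backward(dy, caches[[i]])
    } else if (d$kind == "flatten") {
      dy <- flatten_backward(dy, caches[[i]])
    } else if (d$kind == "reshape_seq") {
      dy <- reshape_seq_backward(dy, caches[[i]])
    } else if (d$kind == "recurrent") {
      r <- recurrent_backward(dy, p, d, caches[[i]], d$input_dim)
      dy <- r$grad_in; grads[[i]] <- r$grads
    } else if (d$kind == "dense") {
      r <- dense_backward(dy, p$W, caches[[i]], d$activation,
                          pre_activation_grad = (i == n))
      dy <- r$grad_in; grads[[i]] <- r$grads
    } else if (d$kind == "dropout") {
      dy <- dropout_backward(dy, caches[[i]])
    }
  }
  grads
}

# ---- Adam -----------------------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map3 <- function(f, a, b, cc) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- tree_map3(f, a[[k]], b[[k]], cc[[k]])
    out
  } else f(a, b, cc)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    state$m[[i]] <- tree_map3(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                              state$m[[i]], grads[[i]], grads[[i]])
    state$v[[i]] <- tree_map3(function(v, g, ...) beta2 * v + (1 - beta2) * g^2,
                              state$v[[i]], grads[[i]], grads[[i]])
    corr <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
    params[[i]] <- tree_map3(function(p, m, v) {
      upd <- p - corr * m / (sqrt(v) + eps)
      attributes(upd) <- attributes(p)
      upd
    }, params[[i]], state$m[[i]], state$v[[i]])
  }
  list(params = params, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration
#'
#' Defaults follow the study regime: Adam with learning rate 0.001, binary
#' cross-entropy, batch size 16, stratified 80-20 train/validation split.
#' `epochs = NULL` uses the per-architecture default (50 for CNN_LSTM, 20
#' otherwise).
#'
#' @param epochs Number of epochs, or `NULL` for the architecture default.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param validation_split Held-out fraction (stratified).
#' @param seed Integer seed controlling init, split, shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = NULL, batch_size = 16,
                         learning_rate = 0.001, validation_split = 0.2,
                         seed = 1) {
  if (validation_split <= 0 || validation_split >= 1) {
    dv_stop("dysvoice_error_bad_params", "validation_split must be in (0,1)")
  }
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate,
                 validation_split = validation_split, seed = seed),
            class = "train_config")
}

# Stratified index split preserving the class ratio within one item.
stratified_split <- function(y, frac_val) {
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- round(length(idx) * frac_val)
    val <- c(val, sample(idx)[seq_len(n_val)])
  }
  sort(val)
}

#' Train a deep classifier
#'
#' Seeded, deterministic-given-seed minibatch training with Adam and binary
#' cross-entropy on log-mel grids. Records per-epoch training and
#' validation loss/accuracy.
#'
#' @param spec A `model_spec` from [build_model()].
#' @param x Array of inputs `(n, timesteps, mel_bands)` (e.g. from
#'   [corpus_mel_array()]).
#' @param y Binary labels (1 = PD).
#' @param config A [train_config()].
#' @return A `dysvoice_deep` trained model: spec, fitted parameters,
#'   `history` data.frame.
#' @export
train_model <- function(spec, x, y, config = train_config()) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    dv_stop("dysvoice_error_one_class", "training data contains one class")
  }
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1)
  if (!all(dim(x)[2:3] == spec$input_shape)) {
    dv_stop("dysvoice_error_bad_shape",
            "input grid %s does not match model input %s",
            paste(dim(x)[2:3], collapse = "x"),
            paste(spec$input_shape, collapse = "x"))
  }
  epochs <- if (is.null(config$epochs)) {
    if (spec$name == "CNN_LSTM") 50L else 20L
  } else config$epochs
  with_seed(config$seed, {
    net <- nn_init(spec, seed = sample.int(1e9, 1))
    val_idx <- stratified_split(y, config$validation_split)
    tr_idx <- setdiff(seq_along(y), val_idx)
    xtr <- x[tr_idx, , , , drop = FALSE]; ytr <- y[tr_idx]
    xval <- x[val_idx, , , , drop = FALSE]; yval <- y[val_idx]
    # per-feature standardization with training-set statistics: the raw dB
    # grids share a large common-mode component that otherwise dominates
    # the gradient direction and stalls optimization
    norm <- grid_norm_fit(xtr)
    xtr <- grid_norm_apply(xtr, norm)
    xval <- grid_norm_apply(xval, norm)
    state <- list(m = tree_map(function(a) a * 0, net$params),
                  v = tree_map(function(a) a * 0, net$params))
    t_step <- 0
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(length(ytr))
      batch_losses <- c(); batch_accs <- c()
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        xb <- xtr[idx, , , , drop = FALSE]; yb <- ytr[idx]
        fw <- nn_forward(net, xb, training = TRUE)
        p <- as.numeric(fw$out)
        dy <- matrix((p - yb) / length(yb), ncol = 1)
        grads <- nn_backward(net, fw$caches, dy)
        t_step <- t_step + 1
        upd <- adam_step(net$params, grads, state,
                         config$learning_rate, t_step)
        net$params <- upd$params; state <- upd$state
        batch_losses <- c(batch_losses, bce_loss(p, yb))
        batch_accs <- c(batch_accs, mean((p >= 0.5) == yb))
      }
      pv <- as.numeric(nn_forward(net, xval, training = FALSE)$out)
      hist[[ep]] <- data.frame(
        epoch = ep, loss = mean(batch_losses), acc = mean(batch_accs),
        val_loss = bce_loss(pv, yval), val_acc = mean((pv >= 0.5) == yval))
    }
    structure(list(spec = spec, net = net, history = do.call(rbind, hist),
                   config = config, val_idx = val_idx, norm = norm),
              class = c("dysvoice_deep", "dysvoice_model"))
  })
}

#' Predicted class probabilities
#'
#' @param model A fitted model ([train_model()] or [fit_classical()]).
#' @param x New inputs in the representation the model was trained on.
#' @return Numeric vector of P(PD) in (0, 1); class 1 iff >= 0.5.
#' @export
predict_proba <- function(model, x) UseMethod("predict_proba")

#' @export
predict_proba.dysvoice_deep <- function(model, x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1)
  if (length(dim(x)) != 4) dv_stop("dysvoice_error_bad_shape", "need a grid batch")
  if (!is.null(model$norm)) x <- grid_norm_apply(x, model$norm)
  as.numeric(nn_forward(model$net, x, training = FALSE)$out)
}

grid_norm_fit <- function(x) {
  m <- matrix(x, dim(x)[1])
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  scl[!is.finite(scl) | scl < 1e-6] <- 1
  list(center = ctr, scale = scl)
}

grid_norm_apply <- function(x, norm) {
  d <- dim(x)
  m <- matrix(x, d[1])
  m <- sweep(sweep(m, 2, norm$center), 2, norm$scale, "/")
  array(m, d)
}

#' Total trainable parameter count
#'
#' @param model A `dysvoice_deep` model or the result of [build_model()]
#'   (initialized internally for counting).
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  params <- if (inherits(model, "dysvoice_deep")) model$net$params
            else nn_init(model, seed = 1)$params
  total <- 0
  tree_map(function(a) { total <<- total + length(a); NULL }, params)
  total
}

#' Stack corpus mel spectrograms into a model-input array
#'
#' @param corpus A `labeled_corpus`.
#' @param n_mels,n_frames Grid geometry (defaults 128 x 40).
#' @param ... Passed to [mel_spectrogram()].
#' @return List: `x` array `(n, n_frames, n_mels)`, `y` binary labels.
#' @export
corpus_mel_array <- function(corpus, n_mels = 128, n_frames = 40, ...) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  n <- length(corpus$signals)
  x <- array(0, c(n, n_frames, n_mels))
  for (i in seq_len(n)) {
    m <- mel_spectrogram(corpus$signals[[i]], n_mels = n_mels,
                         n_frames = n_frames, ...)
    x[i, , ] <- t(m$values)
  }
  # scale dB grids to [0, 1] for stable optimization
  x <- (x - min(x)) / max(max(x) - min(x), 1e-12)
  list(x = x, y = as.integer(corpus$manifest$label == "PD"))
}
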