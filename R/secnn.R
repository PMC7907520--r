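#' Squeeze-and-excitation block parameters
#'
#' The SE block is a channel-attention unit. For a feature tensor with C
#' channels it first *squeezes* each channel to its global spatial mean,
#' giving a channel descriptor z; then *excites* with a two-layer bottleneck
#' gate s = sigmoid(W2 relu(W1 z)) where W1 is (C/r) x C and W2 is C x (C/r)
#' (r is the reduction ratio); finally each channel is rescaled by its gate
#' value. The inner nonlinearity is ReLU and the outer one is the logistic
#' sigmoid, so every gate lies strictly in (0, 1) and can recalibrate
#' channel responses.
#'
#' @param W1 Bottleneck matrix, (C/r) x C.
#' @param W2 Expansion matrix, C x (C/r).
#' @return An object of class `se_block_params` with elements `W1`, `W2`,
#'   `channels`, `reduction`.
#' @export
se_block_params <- function(W1, W2) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  C <- ncol(W1)
  Cr <- nrow(W1)
  if (nrow(W2) != C || ncol(W2) != Cr) {
    stop("inconsistent SE shapes: W1 is ", Cr, "x", C,
         ", W2 must be ", C, "x", Cr)
  }
  if (C %% Cr != 0) stop("channels (", C, ") not divisible by bottleneck (", Cr, ")")
  structure(list(W1 = W1, W2 = W2, channels = C, reduction = C %/% Cr),
            class = "se_block_params")
}

#' SE block operations
#'
#' `se_squeeze` averages each channel of an H x W x C tensor over its
#' spatial plane; `se_excite` maps the channel descriptor through the
#' bottleneck gate; `se_scale` rescales each channel by its gate value;
#' `se_block` is the composition of the three.
#'
#' @param u Numeric array H x W x C (a single feature tensor).
#' @param z Numeric C-vector (channel descriptor).
#' @param params An [se_block_params()].
#' @param s Numeric C-vector of gate values.
#' @return `se_squeeze`: C-vector. `se_excite`: C-vector in (0,1).
#'   `se_scale`, `se_block`: array of the same shape as `u`.
#' @export
se_squeeze <- function(u) {
  d <- dim(u)
  if (length(d) != 3 || d[1] < 1 || d[2] < 1 || d[3] < 1) {
    stop("u must be a non-empty H x W x C array")
  }
  um <- u
  dim(um) <- c(d[1] * d[2], d[3])
  .colMeans(um, d[1] * d[2], d[3])
}

#' @rdname se_squeeze
#' @export
se_excite <- function(z, params) {
  stopifnot(inherits(params, "se_block_params"))
  if (length(z) != params$channels) {
    stop("z has length ", length(z), ", expected ", params$channels)
  }
  as.vector(sigmoid(params$W2 %*% relu(params$W1 %*% z)))
}

#' @rdname se_squeeze
#' @export
se_scale <- function(u, s) {
  d <- dim(u)
  if (length(d) != 3) stop("u must be an H x W x C array")
  if (length(s) != d[3]) stop("gate length ", length(s), " != channels ", d[3])
  u * rep(s, each = d[1] * d[2])
}

#' @rdname se_squeeze
#' @export
se_block <- function(u, params) {
  se_scale(u, se_excite(se_squeeze(u), params))
}

#' Binary cross-entropy loss and its gradient
#'
#' `bce_loss` is the summed binary cross-entropy
#' `-sum(y log p + (1 - y) log(1 - p))` (natural log); `bce_grad` is its
#' per-sample derivative with respect to the predicted probabilities,
#' `-(y/p - (1 - y)/(1 - p))`. Predicted probabilities are clipped to
#' `[eps, 1 - eps]` before the logs.
#'
#' @param y_pred Predicted probabilities in (0, 1).
#' @param y_true Binary 0/1 labels.
#' @param reduce `"sum"` (the loss as defined) or `"mean"` (per-sample
#'   average, used in training histories).
#' @param eps Clipping constant, default 1e-7.
#' @return `bce_loss`: a scalar. `bce_grad`: a vector, one gradient per
#'   sample.
#' @export
bce_loss <- function(y_pred, y_true, reduce = c("sum", "mean"), eps = 1e-7) {
  reduce <- match.arg(reduce)
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  ll <- -(y_true * log(p) + (1 - y_true) * log(1 - p))
  if (reduce == "sum") sum(ll) else mean(ll)
}

#' @rdname bce_loss
#' @export
bce_grad <- function(y_pred, y_true, eps = 1e-7) {
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -(y_true / p - (1 - y_true) / (1 - p))
}

#' Convolutional stack configuration
#'
#' Architecture knobs for the compact two-convolutional-layer models. The
#' default 2D stack is: conv 3x3x32 (same padding, ReLU) -> SE(r = 8) ->
#' 2x2 max pool -> conv 3x3x64 -> SE(r = 8) -> 2x2 max pool -> flatten ->
#' dropout 0.5 -> dense 64 (ReLU) -> dense 1 (sigmoid). The plain CNN is
#' identical with the two SE blocks removed; the 1D variant runs the same
#' machinery on a k x 1 "image" of the rank-ordered feature vector with a
#' max pool after the first convolution and an average pool after the
#' second.
#'
#' @param input_side Side of the square input mapping (the 1D model uses
#'   `input_side^2` as its vector length).
#' @param filters Integer vector of length 2, filters per conv layer.
#' @param kernel_size Odd kernel size (k x k in 2D, k x 1 in 1D).
#' @param pool_size Pooling window (applied along both axes in 2D, along
#'   the feature axis in 1D).
#' @param pool_kinds Character vector of length 2, `"max"` or `"avg"` per
#'   pooling layer.
#' @param use_se Include the two SE blocks.
#' @param se_reduction SE reduction ratio r; each filter count must be
#'   divisible by it.
#' @param dropout_rate Dropout rate before the dense head, in `[0, 1)`.
#' @param dense_units Width of the penultimate dense layer.
#' @return An object of class `conv_stack_config`.
#' @export
conv_stack_config <- function(input_side = 28, filters = c(32, 64),
                              kernel_size = 3, pool_size = 2,
                              pool_kinds = c("max", "max"), use_se = TRUE,
                              se_reduction = 8, dropout_rate = 0.5,
                              dense_units = 64) {
  cfg <- list(
    n_conv_layers = 2L,
    input_side = as.integer(input_side),
    filters = as.integer(filters),
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size),
    pool_kinds = pool_kinds,
    use_se = isTRUE(use_se),
    se_reduction = as.integer(se_reduction),
    dropout_rate = dropout_rate,
    dense_units = as.integer(dense_units)
  )
  if (length(cfg$filters) != 2) stop("filters must have length 2 (two conv layers)")
  if (cfg$kernel_size %% 2 != 1) stop("kernel_size must be odd (same padding)")
  if (!all(pool_kinds %in% c("max", "avg")) || length(pool_kinds) != 2) {
    stop("pool_kinds must be two of 'max'/'avg'")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stop("dropout_rate in [0,1)")
  if (cfg$use_se && any(cfg$filters %% cfg$se_reduction != 0)) {
    stop("each filter count must be divisible by se_reduction")
  }
  structure(cfg, class = "conv_stack_config")
}

#' Training configuration
#'
#' Minibatch Adam with early stopping: training halts once the validation
#' loss has failed to improve for `patience` consecutive epochs (or at
#' `max_epochs`), and the parameters from the best-validation-loss epoch
#' are restored.
#'
#' @param batch_size Minibatch size (default 50).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param max_epochs Hard cap on epochs (default 200).
#' @param validation_fraction Fraction of the development split held out for
#'   validation when no explicit split is given (default 0.2, stratified).
#' @param seed Integer seed covering shuffling, the validation split and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 50, learning_rate = 0.001, patience = 5,
                         max_epochs = 200, validation_fraction = 0.2,
                         seed = 1) {
  cfg <- list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
              optimizer = "adam", patience = as.integer(patience),
              max_epochs = as.integer(max_epochs),
              validation_fraction = validation_fraction, seed = as.integer(seed))
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  if (cfg$patience < 1) stop("patience must be >= 1")
  if (cfg$max_epochs < 1) stop("max_epochs must be >= 1")
  structure(cfg, class = "train_config")
}

#' Build an untrained classifier
#'
#' @param kind `"secnn"` (with SE blocks), `"cnn"` (same stack without SE)
#'   or `"cnn1d"` (1D stack over the rank-ordered feature vector).
#' @param config A [conv_stack_config()]; defaults to the standard stack for
#'   the chosen kind (for `"cnn"` the SE blocks are dropped; for `"cnn1d"`
#'   the default is filters 16/32, kernel 9, pool 4, max then average
#'   pooling).
#' @param seed Integer seed for the parameter initialization (He-scaled
#'   Gaussians for ReLU layers).
#' @return An object of class `radiomap_model`.
#' @export
build_model <- function(kind = c("secnn", "cnn", "cnn1d"), config = NULL,
                        seed = 1) {
  kind <- match.arg(kind)
  if (is.null(config)) {
    config <- switch(kind,
      secnn = conv_stack_config(),
      cnn = conv_stack_config(use_se = FALSE),
      cnn1d = conv_stack_config(filters = c(16, 32), kernel_size = 9,
                                pool_size = 4, pool_kinds = c("max", "avg"),
                                use_se = FALSE)
    )
  }
  stopifnot(inherits(config, "conv_stack_config"))
  if (kind == "secnn" && !config$use_se) stop("secnn requires use_se = TRUE")
  if (kind != "secnn" && config$use_se) stop(kind, " must have use_se = FALSE")
  dims <- model_input_dims(kind, config)
  ps <- config$pool_size
  if (kind == "cnn1d") {
    if (dims[1] %% (ps * ps) != 0) stop("input length must be divisible by pool_size^2")
  } else {
    if (dims[1] %% (ps * ps) != 0) stop("input side must be divisible by pool_size^2")
  }
  k <- config$kernel_size
  f1 <- config$filters[1]; f2 <- config$filters[2]
  kh <- k
  kw <- if (kind == "cnn1d") 1L else k
  w_div <- if (kind == "cnn1d") 1L else ps * ps
  flat <- (dims[1] %/% (ps * ps)) * (dims[2] %/% w_div) * f2
  r <- config$se_reduction
  params <- with_rng_seed(seed, {
    p <- list(
      K1 = matrix(stats::rnorm(kh * kw * 1 * f1, sd = sqrt(2 / (kh * kw))), kh * kw, f1),
      b1 = numeric(f1),
      K2 = matrix(stats::rnorm(kh * kw * f1 * f2, sd = sqrt(2 / (kh * kw * f1))),
                  kh * kw * f1, f2),
      b2 = numeric(f2),
      Wd1 = matrix(stats::rnorm(config$dense_units * flat, sd = sqrt(2 / flat)),
                   config$dense_units, flat),
      bd1 = numeric(config$dense_units),
      Wd2 = matrix(stats::rnorm(config$dense_units, sd = sqrt(1 / config$dense_units)),
                   1, config$dense_units),
      bd2 = 0
    )
    if (config$use_se) {
      p$S1a <- matrix(stats::rnorm(f1 %/% r * f1, sd = sqrt(2 / f1)), f1 %/% r, f1)
      p$S1b <- matrix(stats::rnorm(f1 * (f1 %/% r), sd = sqrt(1 / (f1 %/% r))),
                      f1, f1 %/% r)
      p$S2a <- matrix(stats::rnorm(f2 %/% r * f2, sd = sqrt(2 / f2)), f2 %/% r, f2)
      p$S2b <- matrix(stats::rnorm(f2 * (f2 %/% r), sd = sqrt(1 / (f2 %/% r))),
                      f2, f2 %/% r)
    }
    p
  })
  structure(
    list(kind = kind, config = config, params = params, kh = kh, kw = kw,
         input_dims = dims, seed = seed),
    class = "radiomap_model"
  )
}

model_input_dims <- function(kind, config) {
  if (kind == "cnn1d") c(config$input_side^2, 1L) else rep(config$input_side, 2L)
}

#' Number of learnable parameters of a model
#'
#' For the SE-CNN this exceeds the plain CNN by `2 C1^2 / r + 2 C2^2 / r`
#' (the two SE bottleneck pairs).
#'
#' @param model A [build_model()] result.
#' @return Integer parameter count.
#' @export
model_param_count <- function(model) {
  stopifnot(inherits(model, "radiomap_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.radiomap_model <- function(x, ...) {
  cat(sprintf("<radiomap_model> kind=%s input=%s params=%d%s\n",
              x$kind, paste(x$input_dims, collapse = "x"),
              model_param_count(x),
              if (!is.null(x$history)) sprintf(" (trained, %d epochs)",
                                               x$stopped_epoch) else ""))
  invisible(x)
}

# Slice model input (feature_map_set or matrix) into an [H, W, 1, nb] batch.
model_input_batch <- function(model, data, idx) {
  if (model$kind == "cnn1d") {
    x <- if (inherits(data, "feature_map_set")) unmap_features(data) else data
    xb <- t(x[idx, , drop = FALSE])
    dim(xb) <- c(nrow(xb), 1L, 1L, length(idx))
  } else {
    stopifnot(inherits(data, "feature_map_set"))
    if (data$side != model$input_dims[1]) {
      stop("mapping side ", data$side, " != model input side ", model$input_dims[1])
    }
    xb <- data$values[, , idx, drop = FALSE]
    dim(xb) <- c(dim(xb)[1], dim(xb)[2], 1L, length(idx))
  }
  xb
}

model_input_n <- function(data) {
  if (inherits(data, "feature_map_set")) length(data$patient_ids) else nrow(data)
}

# Full forward pass. `training` enables dropout (RNG must be seeded by the
# caller); `se_gate` overrides the SE gates (scalar), for ablation checks.
forward_model <- function(model, x, training = FALSE, se_gate = NULL,
                          want_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  ps <- cfg$pool_size
  pw <- if (model$kind == "cnn1d") 1L else ps
  cache <- list()

  c1 <- conv_fw(x, p$K1, p$b1, model$kh, model$kw)
  m1 <- c1$out > 0
  a1 <- c1$out * m1
  if (cfg$use_se) {
    s1 <- se_fw(a1, p$S1a, p$S1b, gate_override = se_gate)
    a1 <- s1$out
  }
  p1 <- pool_fw(a1, ps, pw, cfg$pool_kinds[1])

  c2 <- conv_fw(p1$out, p$K2, p$b2, model$kh, model$kw)
  m2 <- c2$out > 0
  a2 <- c2$out * m2
  if (cfg$use_se) {
    s2 <- se_fw(a2, p$S2a, p$S2b, gate_override = se_gate)
    a2 <- s2$out
  }
  p2 <- pool_fw(a2, ps, pw, cfg$pool_kinds[2])

  xf <- p2$out
  nb <- dim(x)[4]
  dim(xf) <- c(length(xf) %/% nb, nb)
  if (training && cfg$dropout_rate > 0) {
    keep <- (stats::runif(length(xf)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate)
    dim(keep) <- dim(xf)
    xf <- xf * keep
  } else {
    keep <- NULL
  }
  d1pre <- dense_fw(xf, p$Wd1, p$bd1)
  d1 <- pmax(d1pre, 0)
  logits <- dense_fw(d1, p$Wd2, p$bd2)
  prob <- as.vector(sigmoid(logits))

  if (want_cache) {
    cache <- list(c1 = c1, m1 = m1, s1 = if (cfg$use_se) s1, p1 = p1,
                  c2 = c2, m2 = m2, s2 = if (cfg$use_se) s2, p2 = p2,
                  xf = xf, keep = keep, d1pre = d1pre, d1 = d1, prob = prob,
                  nb = nb)
  }
  list(prob = prob, cache = cache)
}

# Gradients of the mean BCE over the batch w.r.t. every parameter.
backward_model <- function(model, cache, y) {
  p <- model$params
  cfg <- model$config
  nb <- cache$nb
  g <- list()

  dlogit <- matrix((cache$prob - y) / nb, 1, nb)
  g$Wd2 <- tcrossprod(dlogit, cache$d1)
  g$bd2 <- sum(dlogit)
  dd1 <- crossprod(p$Wd2, dlogit) * (cache$d1pre > 0)
  g$Wd1 <- tcrossprod(dd1, cache$xf)
  g$bd1 <- rowSums(dd1)
  dxf <- crossprod(p$Wd1, dd1)
  if (!is.null(cache$keep)) dxf <- dxf * cache$keep

  dp2 <- dxf
  dim(dp2) <- dim(cache$p2$out)
  da2 <- pool_bw(dp2, cache$p2$cache)
  if (cfg$use_se) {
    sb2 <- se_bw(da2, cache$s2$cache, p$S2a, p$S2b)
    da2 <- sb2$dx
    g$S2a <- sb2$dW1; g$S2b <- sb2$dW2
  }
  dc2 <- da2 * cache$m2
  cb2 <- conv_bw(dc2, cache$c2, p$K2)
  g$K2 <- cb2$dK; g$b2 <- cb2$db

  dp1 <- cb2$dx
  da1 <- pool_bw(dp1, cache$p1$cache)
  if (cfg$use_se) {
    sb1 <- se_bw(da1, cache$s1$cache, p$S1a, p$S1b)
    da1 <- sb1$dx
    g$S1a <- sb1$dW1; g$S1b <- sb1$dW2
  }
  dc1 <- da1 * cache$m1
  cb1 <- conv_bw(dc1, cache$c1, p$K1)
  g$K1 <- cb1$dK; g$b1 <- cb1$db

  g
}

eval_loss_acc <- function(model, data, y, idx, batch = 256L) {
  n <- length(idx)
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    sl <- start:min(start + batch - 1L, n)
    xb <- model_input_batch(model, data, idx[sl])
    probs[sl] <- forward_model(model, xb)$prob
  }
  list(loss = bce_loss(probs, y[idx], reduce = "mean"),
       acc = mean((probs >= 0.5) == (y[idx] == 1)),
       probs = probs)
}

#' Train a classifier on feature mappings
#'
#' Minibatch Adam on the mean binary cross-entropy, with seeded shuffling
#' and dropout, per-epoch train/validation loss and accuracy tracking,
#' early stopping on the validation loss, and restoration of the
#' best-validation parameters.
#'
#' @param model An untrained [build_model()] result.
#' @param data A [build_feature_maps()] result (or, for `"cnn1d"`, either
#'   that or a patients x features matrix in rank order).
#' @param labels 0/1 vector (or a label data.frame) aligned with `data`.
#' @param tc A [train_config()].
#' @param split Optional list with integer index vectors `train` and `val`
#'   (disjoint). Default: stratified split using
#'   `tc$validation_fraction` and `tc$seed`.
#' @return The model with added elements `history` (data.frame epoch,
#'   train_loss, train_acc, val_loss, val_acc), `stopped_epoch`,
#'   `best_epoch`, `split`, and updated parameters.
#' @export
train_model <- function(model, data, labels, tc = train_config(), split = NULL) {
  stopifnot(inherits(model, "radiomap_model"), inherits(tc, "train_config"))
  y <- if (is.data.frame(labels)) labels$egfr else labels
  n <- model_input_n(data)
  if (length(y) != n) stop("labels not aligned with data")
  if (is.null(split)) {
    split <- stratified_split(y, tc$validation_fraction, tc$seed)
  }
  if (length(split$train) == 0 || length(split$val) == 0) stop("empty split")
  if (length(intersect(split$train, split$val)) > 0) {
    stop("train and validation sets must be disjoint")
  }
  if (length(unique(y[split$train])) < 2) stop("single-class training labels")

  params <- model$params
  state <- adam_init(params)
  history <- vector("list", tc$max_epochs)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L
  stopped_epoch <- tc$max_epochs

  with_rng_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(split$train)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1L, length(ord), by = tc$batch_size)) {
        bidx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
        xb <- model_input_batch(model, data, bidx)
        yb <- y[bidx]
        model$params <- params
        fw <- forward_model(model, xb, training = TRUE, want_cache = TRUE)
        g <- backward_model(model, fw$cache, yb)
        upd <- adam_step(params, g, state, tc$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bce_loss(fw$prob, yb, reduce = "sum")
        ep_correct <- ep_correct + sum((fw$prob >= 0.5) == (yb == 1))
      }
      model$params <- params
      val <- eval_loss_acc(model, data, y, split$val)
      history[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss = ep_loss / length(ord),
        train_acc = ep_correct / length(ord),
        val_loss = val$loss, val_acc = val$acc
      )
      if (val$loss < best_val) {
        best_val <- val$loss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$patience) {
          stopped_epoch <- epoch
          break
        }
      }
    }
  })
  model$params <- best_params
  model$history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  model$stopped_epoch <- stopped_epoch
  model$best_epoch <- best_epoch
  model$train_config <- tc
  model$split <- split
  model
}

#' Predict mutation probabilities
#'
#' Deterministic inference pass (no dropout); probabilities are in `[0, 1]`
#' with higher values meaning more likely EGFR-mutant.
#'
#' @param object A (trained) `radiomap_model`.
#' @param data A [build_feature_maps()] result (or matrix for `"cnn1d"`).
#' @param se_gate Optional scalar overriding every SE gate (used to verify
#'   that forcing the gates open reduces the SE-CNN to the plain CNN).
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return Named numeric vector of probabilities (names = patient ids when
#'   available).
#' @export
predict.radiomap_model <- function(object, data, se_gate = NULL,
                                   batch_size = 256L, ...) {
  n <- model_input_n(data)
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- model_input_batch(object, data, idx)
    probs[idx] <- forward_model(object, xb, se_gate = se_gate)$prob
  }
  if (inherits(data, "feature_map_set")) names(probs) <- data$patient_ids
  else if (!is.null(rownames(data))) names(probs) <- rownames(data)
  probs
}
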