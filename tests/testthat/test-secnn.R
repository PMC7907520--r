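test_that("se_squeeze is the per-channel spatial mean and is linear", {
  u <- array(0, c(2, 2, 1))
  u[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)  # plane [[1,2],[3,4]]
  expect_equal(se_squeeze(u), 2.5)

  v <- array(7, c(3, 5, 4))
  expect_equal(se_squeeze(v), rep(7, 4))

  set.seed(2)
  a <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  b <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  expect_equal(se_squeeze(2 * a + 3 * b),
               2 * se_squeeze(a) + 3 * se_squeeze(b), tolerance = 1e-12)

  expect_error(se_squeeze(array(1, c(2, 2))), "array")
})

test_that("se_excite matches direct evaluation and stays in (0,1)", {
  # zero weights: sigmoid(0) gate
  p0 <- se_block_params(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(se_excite(c(1, -3), p0), c(0.5, 0.5))

  # C = 2, r = 1 with small integer weights, hand-computed:
  # z = (1, 2); W1 z = (1*1 + (-1)*2, 2*1 + 1*2) = (-1, 4); relu = (0, 4)
  # W2 relu = (0*1 + 4*1, 0*2 + 4*(-1)) = (4, -4); sigmoid = (0.98201..., 0.01798...)
  W1 <- matrix(c(1, 2, -1, 1), 2, 2)   # rows (1,-1), (2,1)
  W2 <- matrix(c(1, 2, 1, -1), 2, 2)   # rows (1,1), (2,-1)
  p <- se_block_params(W1, W2)
  expect_equal(se_excite(c(1, 2), p),
               c(1 / (1 + exp(-4)), 1 / (1 + exp(4))), tolerance = 1e-9)

  set.seed(3)
  p_rand <- se_block_params(matrix(rnorm(8), 2, 4), matrix(rnorm(8), 4, 2))
  s <- se_excite(rnorm(4), p_rand)
  expect_true(all(s > 0 & s < 1))
  expect_error(se_excite(rnorm(3), p_rand), "length")
  expect_error(se_block_params(matrix(0, 2, 4), matrix(0, 2, 4)), "shape")
})

test_that("se_scale rescales channel-wise with identity and annihilation limits", {
  set.seed(4)
  u <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_equal(se_scale(u, c(1, 1, 1)), u)
  expect_equal(se_scale(u, c(0, 0, 0)), array(0, dim(u)))
  s <- c(0.2, 1.5, -2)
  out <- se_scale(u, s)
  for (c in 1:3) expect_equal(out[, , c], u[, , c] * s[c])
  expect_error(se_scale(u, c(1, 2)), "channels")
})

test_that("the SE block composition matches a loop-based oracle", {
  set.seed(5)
  for (rep in 1:25) {
    C <- sample(c(2, 4, 6, 8), 1)
    H <- sample(1:8, 1)
    Wd <- sample(1:8, 1)
    r <- sample(c(1, 2), 1)
    u <- array(rnorm(H * Wd * C), c(H, Wd, C))
    W1 <- matrix(rnorm(C / r * C), C / r, C)
    W2 <- matrix(rnorm(C * C / r), C, C / r)
    got <- se_block(u, se_block_params(W1, W2))
    want <- se_block_bruteforce(u, W1, W2)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("binary cross-entropy and its gradient follow the closed forms", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-5)  # perfect prediction limit
  expect_equal(bce_loss(c(0.3, 0.8), c(0, 1), reduce = "mean"),
               (-log(0.7) - log(0.8)) / 2, tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")

  # gradient vs central finite differences at random interior points
  set.seed(6)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95)
    y <- rbinom(1, 1, 0.5)
    h <- 1e-6
    fd <- (bce_loss(p + h, y) - bce_loss(p - h, y)) / (2 * h)
    an <- bce_grad(p, y)
    expect_lt(abs(fd - an) / abs(fd), 1e-4)
  }
})

test_that("model building is seeded, kind-consistent and counts parameters", {
  m1 <- build_model("secnn", tiny_conv_config(), seed = 11)
  m2 <- build_model("secnn", tiny_conv_config(), seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model("secnn", tiny_conv_config(), seed = 12)
  expect_false(identical(m1$params, m3$params))

  # cnn is secnn minus the two SE bottleneck pairs
  cnn <- build_model("cnn", tiny_conv_config(use_se = FALSE), seed = 11)
  f <- tiny_conv_config()$filters
  r <- tiny_conv_config()$se_reduction
  se_terms <- 2 * f[1]^2 / r + 2 * f[2]^2 / r
  expect_equal(model_param_count(m1) - model_param_count(cnn), se_terms)

  # full-size architecture difference
  big_se <- build_model("secnn", seed = 1)
  big_cnn <- build_model("cnn", seed = 1)
  expect_equal(model_param_count(big_se) - model_param_count(big_cnn),
               2 * 32^2 / 8 + 2 * 64^2 / 8)

  expect_error(conv_stack_config(filters = c(6, 8), se_reduction = 4),
               "divisible")
  expect_error(build_model("cnn", tiny_conv_config(use_se = TRUE)), "use_se")

  # forward pass contract: probabilities in (0,1), one per sample
  fx <- make_tiny_mapset(n = 3, side = 8)
  pr <- predict(m1, fx$maps)
  expect_length(pr, 3)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("1D variant consumes the rank-ordered feature vector", {
  fx <- make_tiny_mapset(n = 5, side = 8)
  cfg <- conv_stack_config(input_side = 8, filters = c(4, 8), kernel_size = 9,
                           pool_size = 2, pool_kinds = c("max", "avg"),
                           use_se = FALSE, dense_units = 8)
  m <- build_model("cnn1d", cfg, seed = 2)
  pr_maps <- predict(m, fx$maps)
  pr_mat <- predict(m, unmap_features(fx$maps))
  expect_equal(unname(pr_maps), unname(pr_mat))
  expect_true(all(pr_maps > 0 & pr_maps < 1))
})

test_that("early stopping and history bookkeeping follow the patience rule", {
  fx <- make_tiny_mapset(n = 40, side = 8, seed = 9)
  m <- build_model("secnn", tiny_conv_config(), seed = 1)

  # lr = 0 freezes parameters: flat validation loss from epoch 1, so
  # training stops at epoch 1 + patience
  tc0 <- train_config(batch_size = 10, learning_rate = 0, patience = 3,
                      max_epochs = 50, seed = 5)
  tr0 <- train_model(m, fx$maps, fx$labels, tc0)
  expect_equal(tr0$stopped_epoch, 4L)
  expect_equal(nrow(tr0$history), tr0$stopped_epoch)
  expect_equal(tr0$best_epoch, 1L)

  # patience cannot trigger before max_epochs when max_epochs <= patience
  tc1 <- train_config(batch_size = 10, patience = 5, max_epochs = 3, seed = 5)
  tr1 <- train_model(m, fx$maps, fx$labels, tc1)
  expect_equal(tr1$stopped_epoch, 3L)
  expect_equal(nrow(tr1$history), 3L)

  expect_error(train_model(m, fx$maps, rep(1L, 40), tc1), "single-class")
  expect_error(train_model(m, fx$maps, fx$labels, tc1,
                           split = list(train = 1:20, val = 15:30)),
               "disjoint")
  expect_error(train_model(m, fx$maps, fx$labels, tc1,
                           split = list(train = integer(0), val = 1:5)),
               "empty split")
})

test_that("training is deterministic and learns a separable mapping", {
  fx <- make_tiny_mapset(n = 80, side = 8, d = 3, seed = 10)
  m <- build_model("secnn", tiny_conv_config(), seed = 2)
  tc <- train_config(batch_size = 20, patience = 5, max_epochs = 12, seed = 7)
  tr1 <- train_model(m, fx$maps, fx$labels, tc)
  tr2 <- train_model(m, fx$maps, fx$labels, tc)
  expect_identical(tr1$history, tr2$history)
  expect_identical(tr1$params, tr2$params)

  pr <- predict(tr1, fx$maps)
  expect_identical(pr, predict(tr1, fx$maps))  # inference determinism
  expect_gt(mean(pr[fx$labels == 1]), mean(pr[fx$labels == 0]))
})

test_that("forcing the SE gates open reduces the SE-CNN to the plain CNN", {
  fx <- make_tiny_mapset(n = 6, side = 8)
  se <- build_model("secnn", tiny_conv_config(), seed = 3)
  cnn <- build_model("cnn", tiny_conv_config(use_se = FALSE), seed = 3)
  shared <- intersect(names(cnn$params), names(se$params))
  cnn$params[shared] <- se$params[shared]
  expect_equal(unname(predict(se, fx$maps, se_gate = 1)),
               unname(predict(cnn, fx$maps)), tolerance = 1e-6)
})
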