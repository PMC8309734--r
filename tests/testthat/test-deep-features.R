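expect_layers <- function(model, kinds) {
  expect_equal(vapply(model$layers, `[[`, "", "kind"), kinds)
}

test_that("the MLP builder matches its published table", {
  m <- build_architecture("mlp", c(2560, 1))
  expect_layers(m, c("flatten", "dropout", "dense", "dropout", "dense",
                     "dense"))
  sp <- architecture_spec(m)
  expect_equal(sp$units[c(3, 5, 6)], c(250L, 100L, 2L))
  expect_equal(sp$rate[c(2, 4)], c(0.1, 0.1))
  expect_equal(sp$activation[6], "softmax")
  expect_equal(m$feature_layer, 5L)
  expect_equal(prod(m$layers[[5]]$out_shape), 100)
})

test_that("the CNN builder matches its published table", {
  m <- build_architecture("cnn", c(2560, 1))
  expect_layers(m, c("conv1d", "maxpool1d", "dropout", "conv1d", "maxpool1d",
                     "dropout", "flatten", "dense", "dense"))
  sp <- architecture_spec(m)
  expect_equal(sp$units[c(1, 4)], c(16L, 16L))
  expect_equal(sp$size[c(1, 4)], c(7L, 7L))
  expect_equal(sp$stride[c(1, 4)], c(2L, 2L))
  expect_equal(sp$activation[c(1, 4)], c("relu", "relu"))
  expect_equal(sp$size[c(2, 5)], c(4L, 4L))
  expect_equal(sp$units[c(8, 9)], c(100L, 2L))
  expect_equal(prod(m$layers[[m$feature_layer]]$out_shape), 100)
})

test_that("the ConvLSTM builder matches its published table", {
  m <- build_architecture("convlstm", c(4, 640, 1))
  expect_layers(m, c(rep(c("convlstm", "dropout", "batchnorm", "maxpool1d"), 3),
                     "flatten", "dropout", "dense", "dense"))
  sp <- architecture_spec(m)
  expect_equal(sp$units[c(1, 5, 9)], c(32L, 16L, 8L))
  expect_equal(sp$size[c(1, 5, 9)], c(11L, 7L, 3L))
  expect_equal(sp$stride[c(1, 5, 9)], c(8L, 8L, 2L))
  expect_equal(sp$activation[c(1, 5, 9)], rep("tanh", 3))
  expect_equal(sp$units[c(15, 16)], c(100L, 2L))
  expect_equal(sp$activation[15], "relu")
  expect_equal(prod(m$layers[[m$feature_layer]]$out_shape), 100)
  expect_error(build_architecture("convlstm", c(2560, 1)), "input_shape")
})

test_that("the autoencoder builder matches its published table and restores the input shape", {
  m <- build_architecture("cae", c(2560, 1))
  expect_layers(m, c("conv1d", "maxpool1d", "conv1d", "maxpool1d", "conv1d",
                     "maxpool1d", "upsample1d", "conv1d", "upsample1d",
                     "conv1d", "upsample1d", "conv1d", "conv1d"))
  sp <- architecture_spec(m)
  expect_equal(sp$units[c(1, 3, 5, 8, 10, 12, 13)],
               c(64L, 32L, 16L, 16L, 32L, 64L, 1L))
  expect_equal(sp$size[c(1, 3, 5, 8, 10, 12, 13)],
               c(7L, 11L, 11L, 11L, 11L, 7L, 1L))
  expect_equal(m$output_shape, c(2560, 1))             # reconstruction contract
  expect_equal(prod(m$layers[[m$feature_layer]]$out_shape), 640)  # 2560/4^3*16
  m2 <- build_architecture("cae", c(1408, 1))
  expect_equal(prod(m2$layers[[m2$feature_layer]]$out_shape), 352) # 1408/4^3*16
  expect_equal(m2$output_shape, c(1408, 1))
})

test_that("ConvLSTM reshaping splits time into four parts and is invertible", {
  x <- matrix(seq_len(1408), ncol = 1)
  r <- reshape_for_convlstm(x)
  expect_equal(dim(r), c(4, 352, 1))
  expect_equal(as.numeric(aperm(r, c(2, 1, 3))), as.numeric(x))  # concat restores
  expect_equal(r[2, 1, 1], 353)

  r2 <- reshape_for_convlstm(matrix(0, 2560, 1))
  expect_equal(dim(r2), c(4, 640, 1))
  expect_error(reshape_for_convlstm(matrix(0, 1407, 1)), "not divisible")
})

test_that("supervised training reduces loss on a separable toy set and is reproducible", {
  set.seed(3)
  n <- 24; T_ <- 128
  x <- array(0, c(n, T_, 1)); lab <- rep(c(0, 1), each = n / 2)
  for (i in seq_len(n)) {
    c0 <- if (lab[i] == 0) 32 else 96
    x[i, , 1] <- exp(-(seq_len(T_) - c0)^2 / 100) + rnorm(T_, 0, 0.05)
  }
  cfg <- train_config(learning_rate = 1e-3, epochs = 8, rng_seed = 1)
  fit <- train_supervised(build_architecture("mlp", c(T_, 1), seed = 1), x,
                          lab, cfg)
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  fit2 <- train_supervised(build_architecture("mlp", c(T_, 1), seed = 1), x,
                           lab, cfg)
  expect_identical(fit$loss, fit2$loss)

  # zero epochs: untouched model, empty history
  m0 <- build_architecture("cnn", c(T_, 1), seed = 2)
  fit0 <- train_supervised(m0, x, lab, train_config(epochs = 0))
  expect_identical(fit0$model$layers, m0$layers)
  expect_length(fit0$loss, 0L)

  expect_error(train_supervised(build_architecture("mlp", c(T_, 1)), x,
                                rep(1, n), cfg), "two classes")
  # every classifier architecture trains on the toy set
  fitc <- train_supervised(build_architecture("cnn", c(T_, 1), seed = 1), x,
                           lab, train_config(1e-3, 3, rng_seed = 1))
  expect_lt(fitc$loss[3], fitc$loss[1])
  xl <- array(x, c(n, 4, T_ / 4, 1))
  fitl <- train_supervised(build_architecture("convlstm", c(4, T_ / 4, 1),
                                              seed = 1), xl, lab,
                           train_config(1e-3, 3, rng_seed = 1))
  expect_lt(fitl$loss[3], fitl$loss[1])
})

test_that("autoencoder training drives reconstruction error towards zero on constant windows", {
  x <- array(rep(seq(0.2, 0.8, length.out = 16), each = 64), c(16, 64, 1))
  m <- build_architecture("cae", c(64, 1), seed = 1)
  fit <- train_cae(m, x, train_config(learning_rate = 1e-2, epochs = 30,
                                      rng_seed = 1))
  expect_lt(fit$loss[30], 0.02)
  expect_lt(fit$loss[30], fit$loss[1] / 5)
  fit2 <- train_cae(build_architecture("cae", c(64, 1), seed = 1), x,
                    train_config(1e-2, 30, rng_seed = 1))
  expect_identical(fit$loss, fit2$loss)
})

test_that("truncated extractors are pure functions with the documented output width", {
  set.seed(5)
  x <- array(rnorm(6 * 128), c(6, 128, 1))
  m <- build_architecture("mlp", c(128, 1), seed = 4)
  expect_message(f <- truncate_to_extractor(m), "untrained")
  v <- f(x)
  expect_equal(dim(v), c(6L, 100L))
  expect_true(all(is.finite(v)))
  expect_identical(v, f(x))

  mc <- build_architecture("cae", c(1408, 1), seed = 4)
  fc <- suppressMessages(truncate_to_extractor(mc))
  expect_equal(ncol(fc(array(rnorm(2 * 1408), c(2, 1408, 1)))), 352L)
  expect_equal(attr(fc, "n_features"), 352)
})

test_that("learned features beat a random projection of the same width on separable data", {
  set.seed(6)
  n <- 60; T_ <- 128
  x <- array(0, c(n, T_, 1)); lab <- factor(rep(c(0, 1), n / 2))
  for (i in seq_len(n)) {
    c0 <- if (lab[i] == "0") 32 else 96
    x[i, , 1] <- exp(-(seq_len(T_) - c0)^2 / 100) + rnorm(T_, 0, 0.4)
  }
  tr <- seq_len(n) <= 40; te <- !tr
  fit <- train_supervised(build_architecture("mlp", c(T_, 1), seed = 1),
                          x[tr, , , drop = FALSE], lab[tr],
                          train_config(1e-3, 10, rng_seed = 1))
  fx <- truncate_to_extractor(fit$model)
  acc_of <- function(ftr, fte) {
    rf <- painfex:::with_seed(7, randomForest::randomForest(
      x = ftr, y = droplevels(lab[tr]), ntree = 100))
    mean(predict(rf, fte) == lab[te])
  }
  acc_mlp <- acc_of(fx(x[tr, , , drop = FALSE]), fx(x[te, , , drop = FALSE]))
  P <- painfex:::with_seed(8, matrix(rnorm(T_ * 100), T_, 100))
  xm <- matrix(x, n, T_)
  acc_rp <- acc_of(xm[tr, ] %*% P, xm[te, ] %*% P)
  expect_gte(acc_mlp, acc_rp)
})
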