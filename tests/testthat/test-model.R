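test_that("training configuration enforces the hyperparameter invariants", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 30L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$dropout_rate, 0.2)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$loss, "binary_crossentropy")
  expect_equal(cfg$conv_padding, "same")
  expect_equal(cfg$output_activation, "sigmoid")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(dropout_rate = 1), "dropout")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("analytic gradients match finite differences on a tiny network", {
  m <- build_network(8, train_config(dropout_rate = 0.2), conv_filters = c(2, 3),
                     dense_units = 4, seed = 3)
  set.seed(42)
  n <- 4
  X <- matrix(runif(8 * 8 * 3 * n), ncol = n)
  y <- as.numeric(runif(n) > 0.5)
  mask <- matrix(rbinom(4 * n, 1, 0.8), 4, n)
  p <- m$params
  lossfn <- function(p) {
    tilecover:::cnn_grad_cpp(X, y, 8L, p$conv_W, p$conv_b, p$W1, p$b1,
                             matrix(p$w2, nrow = 1), p$b2, mask, 0.2)$loss
  }
  g <- tilecover:::cnn_grad_cpp(X, y, 8L, p$conv_W, p$conv_b, p$W1, p$b1,
                                matrix(p$w2, nrow = 1), p$b2, mask, 0.2)
  h <- 1e-6
  check <- function(get, set, analytic, k = 8) {
    v <- get(p)
    set.seed(length(v))
    for (i in sample(seq_along(v), min(k, length(v)))) {
      up <- p; vv <- v; vv[i] <- vv[i] + h; up <- set(up, vv)
      dn <- p; vv <- v; vv[i] <- vv[i] - h; dn <- set(dn, vv)
      num <- (lossfn(up) - lossfn(dn)) / (2 * h)
      expect_lt(abs(num - analytic[i]) / max(1e-8, abs(num) + abs(analytic[i])), 1e-5)
    }
  }
  check(function(p) p$conv_W[[1]], function(p, v) { p$conv_W[[1]][] <- v; p },
        as.numeric(g$dconv_W[[1]]))
  check(function(p) p$conv_W[[2]], function(p, v) { p$conv_W[[2]][] <- v; p },
        as.numeric(g$dconv_W[[2]]))
  check(function(p) p$W1, function(p, v) { p$W1[] <- v; p }, as.numeric(g$dW1))
  check(function(p) p$w2, function(p, v) { p$w2[] <- v; p }, as.numeric(g$dw2))
  check(function(p) p$b2, function(p, v) { p$b2 <- v; p }, g$db2, k = 1)
})

test_that("network construction honors shape invariants", {
  m <- build_network(30, train_config(), seed = 1)
  conv_layers <- Filter(function(l) l$type == "conv2d", m$architecture)
  # zero padding: convolution preserves spatial size
  for (l in conv_layers) expect_equal(l$output_hw, l$input_hw)
  expect_equal(m$architecture[[length(m$architecture)]]$activation, "sigmoid")
  expect_error(build_network(4), ">= 8")
  expect_error(build_network(8, conv_filters = c(8, 8, 8, 8)), "pooling")
})

test_that("forward pass yields probabilities invariant to batch partitioning", {
  m <- build_network(30, train_config(), conv_filters = c(4, 8), dense_units = 8, seed = 2)
  set <- separable_tile_set(12, seed = 6)
  all_at_once <- predict_tiles(m, set)
  expect_true(all(all_at_once$probability >= 0 & all_at_once$probability <= 1))
  halves <- rbind(predict_tiles(m, set[1:10, ]), predict_tiles(m, set[11:24, ]))
  expect_equal(all_at_once$probability, halves$probability)
  expect_identical(predict_tiles(m, list()),
                   tibble::tibble(probability = numeric(), call = integer()))
  expect_error(predict_tiles(m, list(uniform_image(c(1, 2, 3), 16))), "expects")
})

test_that("the classifier learns the separable colour task and matches the oracle", {
  set <- separable_tile_set(120, seed = 1)
  m <- build_network(30, train_config(epochs = 5, batch_size = 32),
                     conv_filters = c(8, 16), dense_units = 32, seed = 2)
  m <- train_network(m, set, seed = 3)
  h <- m$history
  expect_equal(nrow(h), 5L)
  expect_true(all(is.finite(h$loss)))
  expect_true(all(is.finite(h$val_loss)))
  expect_gte(max(h$val_accuracy), 0.99)
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])

  oracle <- color_threshold_oracle(set$pixels)
  expect_equal(unname(oracle), set$label)   # sanity: task is separable by colour
  pred <- predict_tiles(m, set)
  expect_gte(mean(pred$call == oracle), 0.99)
})

test_that("training is reproducible under the same seed", {
  set <- separable_tile_set(40, seed = 4)
  fit <- function() {
    m <- build_network(30, train_config(epochs = 2, batch_size = 32),
                       conv_filters = c(4, 8), dense_units = 8, seed = 7)
    train_network(m, set, seed = 8)
  }
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("models persist and reload with identical predictions", {
  fit <- cached_small_fit()
  dir <- withr::local_tempdir()
  save_model(fit$model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  expect_true(file.exists(file.path(dir, "history.csv")))
  back <- load_model(dir)
  expect_identical(back$architecture, fit$model$architecture)
  probe <- fit$dataset[1:20, ]
  expect_identical(predict_tiles(back, probe), predict_tiles(fit$model, probe))
})

test_that("training rejects degenerate inputs", {
  set <- separable_tile_set(10, seed = 2)
  m <- build_network(30, train_config(epochs = 1), conv_filters = c(4), dense_units = 4, seed = 1)
  no_val <- set; no_val$split <- "train"
  expect_error(train_network(m, no_val, seed = 1), "validation")
  expect_error(train_network(m, set[0, ], seed = 1), "split|empty")
})

test_that("tidy and glance summarize a fitted classifier", {
  fit <- cached_small_fit()
  td <- tidy(fit$model)
  expect_named(td, c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))
  expect_equal(nrow(td), fit$model$config$epochs)
  gl <- glance(fit$model)
  expect_equal(gl$epochs_trained, fit$model$config$epochs)
  expect_gt(gl$n_parameters, 1000)
  expect_s3_class(autoplot(fit$model), "ggplot")
})
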