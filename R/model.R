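#' Training hyperparameters for the tile classifier
#'
#' Defaults are the study settings for goldenrod tile classification:
#' 30 epochs, batch size 128, dropout 0.2, Adam with learning rate 0.001,
#' binary cross-entropy loss, ReLU hidden activations, zero ("same")
#' convolution padding and a single sigmoid output unit.
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size tiles per gradient step (>= 1).
#' @param dropout_rate dropout probability on the dense hidden layer, `[0, 1)`.
#' @param learning_rate Adam step size (> 0).
#' @param threshold sigmoid probability at or above which a tile is called
#'   positive.
#' @return a `train_config` object. Fixed descriptive fields record the
#'   optimizer (`"adam"`), loss (`"binary_crossentropy"`), padding
#'   (`"same"`), hidden activation (`"relu"`) and output activation
#'   (`"sigmoid"`).
#' @export
train_config <- function(epochs = 30, batch_size = 128, dropout_rate = 0.2,
                         learning_rate = 0.001, threshold = 0.5) {
  if (!is_count(epochs)) abort("`epochs` must be a whole number >= 1")
  if (!is_count(batch_size)) abort("`batch_size` must be a whole number >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must lie in [0, 1)")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      dropout_rate = dropout_rate, learning_rate = learning_rate,
      threshold = threshold,
      optimizer = "adam", loss = "binary_crossentropy",
      conv_padding = "same", hidden_activation = "relu",
      output_activation = "sigmoid"
    ),
    class = "train_config"
  )
}

# layer-by-layer description; round-trips through serialization
arch_descriptor <- function(tile_size, conv_filters, dense_units, dropout_rate) {
  layers <- list()
  h <- tile_size; c_in <- 3L
  for (f in conv_filters) {
    layers <- c(layers, list(
      list(type = "conv2d", kernel = c(3L, 3L), filters = as.integer(f),
           padding = "same", activation = "relu",
           input_hw = c(h, h), output_hw = c(h, h)),
      list(type = "maxpool2d", pool = c(2L, 2L),
           input_hw = c(h, h), output_hw = c(h %/% 2L, h %/% 2L))
    ))
    h <- h %/% 2L
    c_in <- as.integer(f)
  }
  c(
    layers,
    list(
      list(type = "flatten", units = h * h * c_in),
      list(type = "dense", units = as.integer(dense_units), activation = "relu"),
      list(type = "dropout", rate = dropout_rate),
      list(type = "dense", units = 1L, activation = "sigmoid")
    )
  )
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build the shallow convolutional tile classifier (untrained)
#'
#' The network is deliberately shallow — the inputs are tiny tile crops, not
#' whole scenes. Default architecture: two blocks of 3x3 same-padded
#' convolution (32 then 64 filters, ReLU) each followed by 2x2 max pooling,
#' a flatten, a 64-unit ReLU dense layer with dropout, and a single sigmoid
#' output giving the probability that the tile contains the target flower.
#'
#' @param tile_size side of the square input tile in pixels (>= 8).
#' @param config a [train_config()].
#' @param conv_filters integer vector: filters per convolution block.
#' @param dense_units width of the dense hidden layer.
#' @param seed RNG seed for weight initialization (Glorot-uniform).
#' @return a `tile_cnn` object holding the parameters, architecture
#'   descriptor and (after [train_network()]) the training history.
#' @export
build_network <- function(tile_size = 30, config = train_config(),
                          conv_filters = c(32, 64), dense_units = 64,
                          seed = 1) {
  stopifnot(inherits(config, "train_config"))
  if (!is_count(tile_size) || tile_size < 8) {
    abort("`tile_size` must be a whole number >= 8")
  }
  if (length(conv_filters) < 1) abort("need at least one convolution block")
  if (tile_size %/% 2^length(conv_filters) < 1) {
    abort(sprintf(
      "tile size %d is too small for %d pooling steps", tile_size, length(conv_filters)
    ))
  }
  maybe_seed(seed)
  c_in <- 3L
  h <- as.integer(tile_size)
  conv_W <- list(); conv_b <- list()
  for (f in conv_filters) {
    conv_W <- c(conv_W, list(glorot(f, 9 * c_in, 9 * c_in, 9 * f)))
    conv_b <- c(conv_b, list(rep(0, f)))
    c_in <- as.integer(f)
    h <- h %/% 2L
  }
  flat <- h * h * c_in
  params <- list(
    conv_W = conv_W, conv_b = conv_b,
    W1 = glorot(dense_units, flat, flat, dense_units),
    b1 = rep(0, dense_units),
    w2 = glorot(1, dense_units, dense_units, 1),
    b2 = 0
  )
  structure(
    list(
      tile_size = as.integer(tile_size),
      conv_filters = as.integer(conv_filters),
      dense_units = as.integer(dense_units),
      config = config,
      params = params,
      architecture = arch_descriptor(tile_size, conv_filters, dense_units,
                                     config$dropout_rate),
      history = NULL,
      trained = FALSE
    ),
    class = "tile_cnn"
  )
}

#' @export
print.tile_cnn <- function(x, ...) {
  cat(sprintf(
    "<tile_cnn> %d px tiles | conv blocks: %s | dense %d | %s\n",
    x$tile_size, paste(x$conv_filters, collapse = "-"), x$dense_units,
    if (x$trained) sprintf("trained %d epochs", nrow(x$history)) else "untrained"
  ))
  invisible(x)
}

forward_probs <- function(model, X) {
  p <- model$params
  as.numeric(cnn_forward_cpp(
    X, model$tile_size, p$conv_W, p$conv_b, p$W1, p$b1,
    matrix(p$w2, nrow = 1), p$b2
  ))
}

# recursive Adam over the nested parameter list
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(
        p = purrr::map(out, "p"), m = purrr::map(out, "m"), v = purrr::map(out, "v")
      )
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v))
}

zero_like <- function(p) {
  if (is.list(p)) purrr::map(p, zero_like) else p * 0
}

bce_loss <- function(prob, y) {
  p <- clamp(prob, 1e-12, 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the tile classifier
#'
#' Runs mini-batch Adam over an augmented stream of training tiles for
#' exactly `config$epochs` epochs, evaluating loss and thresholded accuracy
#' on the validation tiles after each epoch. Training is reproducible: all
#' randomness (batch composition, augmentation draws, dropout masks) is
#' driven by `seed`.
#'
#' @param model an untrained (or previously trained) [build_network()] model.
#' @param data a `tile_set` with a `split` column (rows tagged `train` /
#'   `validation`), or a list with elements `train` and `validation`, each a
#'   tibble with `pixels` and `label`.
#' @param config a [train_config()]; defaults to the one the model was
#'   built with.
#' @param augment an [augment_config()] applied to training batches;
#'   `NULL` disables augmentation (tiles only rescaled to `[0, 1]`).
#' @param seed RNG seed for the run.
#' @param verbose print one line per epoch.
#' @return the model with fitted parameters, `trained = TRUE` and a
#'   `history` tibble (`epoch`, `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy`).
#' @export
train_network <- function(model, data, config = model$config,
                          augment = augment_config(), seed = 1,
                          verbose = FALSE) {
  stopifnot(inherits(model, "tile_cnn"), inherits(config, "train_config"))
  if (is.data.frame(data)) {
    if (!"split" %in% names(data)) abort("`data` needs a `split` column (train/validation)")
    data <- list(
      train = data[data$split == "train", ],
      validation = data[data$split == "validation", ]
    )
  }
  train_set <- data$train
  val_set <- data$validation
  if (is.null(train_set) || nrow(train_set) == 0) abort("empty training set")
  if (is.null(val_set) || nrow(val_set) == 0) abort("empty validation set")

  maybe_seed(seed)
  if (is.null(augment)) {
    augment <- augment_config(0, 0, FALSE, 0)
  }
  stream <- augment_stream(train_set, augment, seed = sample.int(.Machine$integer.max, 1))

  Xval <- tiles_to_matrix(val_set)
  yval <- as.integer(val_set$label)
  thr <- config$threshold

  p <- model$params
  state <- list(m = zero_like(p), v = zero_like(p))
  n_train <- nrow(train_set)
  steps <- max(1L, ceiling(n_train / config$batch_size))
  history <- vector("list", config$epochs)
  t_adam <- 0L

  for (epoch in seq_len(config$epochs)) {
    batch_loss <- numeric(steps)
    batch_acc <- numeric(steps)
    for (s in seq_len(steps)) {
      b <- stream$next_batch(config$batch_size)
      X <- matrix(b$x, ncol = dim(b$x)[4])
      y <- b$label
      mask <- if (config$dropout_rate > 0) {
        matrix(rbinom(model$dense_units * length(y), 1, 1 - config$dropout_rate),
               model$dense_units, length(y))
      } else {
        matrix(1, model$dense_units, length(y))
      }
      g <- cnn_grad_cpp(X, as.numeric(y), model$tile_size,
                        p$conv_W, p$conv_b, p$W1, p$b1,
                        matrix(p$w2, nrow = 1), p$b2,
                        mask, config$dropout_rate)
      t_adam <- t_adam + 1L
      grads <- list(conv_W = g$dconv_W, conv_b = g$dconv_b,
                    W1 = g$dW1, b1 = as.numeric(g$db1),
                    w2 = g$dw2, b2 = g$db2)
      upd <- adam_step(p, grads, state, config$learning_rate, t_adam)
      p <- upd$params
      p$b1 <- as.numeric(p$b1)
      p$conv_b <- purrr::map(p$conv_b, as.numeric)
      p$b2 <- as.numeric(p$b2)
      state <- upd$state
      batch_loss[s] <- g$loss
      batch_acc[s] <- mean((g$prob >= thr) == (y == 1))
    }
    model$params <- p
    val_prob <- predict_probs_matrix(model, Xval)
    history[[epoch]] <- tibble(
      epoch = epoch,
      loss = mean(batch_loss),
      accuracy = mean(batch_acc),
      val_loss = bce_loss(val_prob, yval),
      val_accuracy = mean((val_prob >= thr) == (yval == 1))
    )
    if (verbose) {
      message(sprintf(
        "epoch %2d/%d  loss %.4f acc %.4f  val_loss %.4f val_acc %.4f",
        epoch, config$epochs, history[[epoch]]$loss, history[[epoch]]$accuracy,
        history[[epoch]]$val_loss, history[[epoch]]$val_accuracy
      ))
    }
  }
  model$params <- p
  model$config <- config
  model$history <- dplyr::bind_rows(history)
  model$trained <- TRUE
  model
}

# forward pass in memory-bounded slabs
predict_probs_matrix <- function(model, X, block = 512L) {
  n <- ncol(X)
  if (n == 0) return(numeric())
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    out[start:end] <- forward_probs(model, X[, start:end, drop = FALSE])
  }
  out
}

#' Classify tiles with a trained model
#'
#' @param model a trained `tile_cnn` (or any function mapping a list of raw
#'   `0–255` tiles to probabilities, useful for plugging in reference
#'   classifiers).
#' @param tiles a `tile_set` tibble, a list of `t x t x 3` arrays
#'   (intensities `0–255`), or a `t x t x 3 x n` array. Intensities are
#'   rescaled by 1/255 internally.
#' @param threshold probability cut-off for the positive call; defaults to
#'   the model's training configuration.
#' @return a tibble with columns `probability` (in `[0, 1]`) and `call`
#'   (integer 0/1), one row per tile in input order.
#' @export
predict_tiles <- function(model, tiles, threshold = NULL) {
  UseMethod("predict_tiles")
}

#' @export
predict_tiles.tile_cnn <- function(model, tiles, threshold = NULL) {
  thr <- threshold %||% model$config$threshold
  X <- tiles_to_matrix(tiles)
  if (ncol(X) == 0) return(tibble(probability = numeric(), call = integer()))
  if (nrow(X) != 3 * model$tile_size^2) {
    abort(sprintf(
      "tiles have %d values each; the model expects %d x %d x 3 = %d",
      nrow(X), model$tile_size, model$tile_size, 3 * model$tile_size^2
    ))
  }
  prob <- predict_probs_matrix(model, X)
  tibble(probability = prob, call = as.integer(prob >= thr))
}

#' @export
predict_tiles.function <- function(model, tiles, threshold = NULL) {
  threshold <- threshold %||% 0.5
  if (is.data.frame(tiles)) tiles <- tiles$pixels
  if (is.array(tiles) && length(dim(tiles)) == 4) {
    tiles <- purrr::map(seq_len(dim(tiles)[4]), function(i) tiles[, , , i, drop = TRUE])
  }
  if (length(tiles) == 0) return(tibble(probability = numeric(), call = integer()))
  prob <- as.numeric(model(tiles))
  tibble(probability = prob, call = as.integer(prob >= threshold))
}

#' @export
predict.tile_cnn <- function(object, newdata, ...) {
  predict_tiles(object, newdata, ...)$probability
}

#' Persist / restore a trained tile classifier
#'
#' The fitted object is written as an RDS file next to a human-readable
#' JSON sidecar describing the architecture, hyperparameters and training
#' history.
#'
#' @param model a `tile_cnn`.
#' @param dir output directory (created if missing).
#' @return `save_model`: `dir`, invisibly. `load_model`: the restored
#'   `tile_cnn`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "tile_cnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  side <- list(
    tile_size = model$tile_size,
    conv_filters = model$conv_filters,
    dense_units = model$dense_units,
    architecture = model$architecture,
    config = unclass(model$config),
    trained = model$trained
  )
  jsonlite::write_json(side, file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}

#' @export
tidy.tile_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), loss = numeric(), accuracy = numeric(),
                  val_loss = numeric(), val_accuracy = numeric()))
  }
  x$history
}

#' @export
glance.tile_cnn <- function(x, ...) {
  h <- x$history
  tibble(
    tile_size = x$tile_size,
    n_conv_blocks = length(x$conv_filters),
    n_parameters = sum(rapply(x$params, length, how = "unlist")),
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_val_accuracy = if (is.null(h)) NA_real_ else h$val_accuracy[nrow(h)]
  )
}

#' @export
autoplot.tile_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
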