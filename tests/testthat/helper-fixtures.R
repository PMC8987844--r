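# Shared fixtures and independent oracles. Expensive fixtures (trained
# models, experiment runs) are memoised so several test files can assert on
# the same computation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# ---- simple image builders -------------------------------------------------

uniform_image <- function(color, h = 30, w = h) {
  arr <- array(0, c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- color[ch]
  arr
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

# noisy single-colour 30 px tiles, the linearly separable toy task
separable_tile_set <- function(n_per_class = 120, seed = 1) {
  set.seed(seed)
  mk <- function(color, n, label) {
    tibble::tibble(
      source_id = sprintf("sep%d", label),
      grid_row = seq_len(n) - 1L, grid_col = 0L,
      pixels = lapply(seq_len(n), function(i) {
        a <- array(0, c(30, 30, 3))
        for (ch in 1:3) a[, , ch] <- pmin(255, pmax(0, color[ch] + rnorm(900, 0, 20)))
        a
      }),
      label = label
    )
  }
  out <- dplyr::bind_rows(
    mk(c(200, 180, 30), n_per_class, 1L),   # flower yellow
    mk(c(45, 110, 40), n_per_class, 0L)     # foliage green
  )
  n_val <- max(1L, round(0.2 * n_per_class))
  out$split <- rep(c(rep("train", n_per_class - n_val), rep("validation", n_val)), 2)
  out
}

# mean-channel colour rule: yellow tiles have high R+G and low B
color_threshold_oracle <- function(tiles) {
  vapply(tiles, function(a) {
    m <- apply(a, 3, mean)
    as.numeric((m[1] + m[2]) / 2 - m[3] > 60)
  }, numeric(1))
}

# ---- independent oracles ---------------------------------------------------

# brute-force position enumeration: the reference for chop_image
brute_chop <- function(image, tile, overlap) {
  s <- as.integer(round(tile * (1 - overlap)))
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- list()
  if (H >= tile && W >= tile) {
    for (y0 in seq(0L, H - tile, by = s)) {
      for (x0 in seq(0L, W - tile, by = s)) {
        out[[length(out) + 1L]] <- image[y0 + seq_len(tile), x0 + seq_len(tile), , drop = FALSE]
      }
    }
  }
  out
}

# direct-arithmetic reference for the four metrics
metrics_oracle <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fn) * (tn + fp)) / n^2
  list(
    accuracy = po,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    kappa = if (pe < 1) (po - pe) / (1 - pe) else if (po == 1) 1 else NA_real_
  )
}

# brute-force per-cell fusion: mean over every tile whose footprint covers
# the cell, reference for aggregate_cells
brute_cells <- function(grid, probs, threshold = 0.5) {
  k <- grid$tile_size_px %/% grid$stride_px
  nr <- grid$n_rows + k - 1L
  nc <- grid$n_cols + k - 1L
  P <- matrix(probs, grid$n_rows, grid$n_cols, byrow = TRUE)
  prob <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rs <- max(1L, i - k + 1L):min(grid$n_rows, i)
      cs <- max(1L, j - k + 1L):min(grid$n_cols, j)
      prob[i, j] <- mean(P[rs, cs])
    }
  }
  list(prob = prob, call = prob >= threshold)
}

# ---- shared experiment fixtures -------------------------------------------

small_train_config <- function(epochs = 6) train_config(epochs = epochs, batch_size = 64)

small_model_for <- function(camera, seed) {
  corpus <- make_corpus(24, scene_spec(camera = camera),
                        length_range = c(10, 160), cover_range = c(0.15, 0.6),
                        seed = seed)
  dataset <- build_dataset_from_corpus(corpus, n_per_class = 400, seed = seed + 1)
  model <- build_network(30, small_train_config(), conv_filters = c(8, 16),
                         dense_units = 32, seed = seed + 2)
  model <- train_network(model, dataset, seed = seed + 2)
  list(corpus = corpus, dataset = dataset, model = model, seed = seed)
}

cached_small_fit <- function() memo("small_fit", small_model_for(camera_profile("camA"), 11000))

distractor_scenes <- function(camera, n, seed0) {
  scenes <- lapply(seq_len(n), function(j) {
    make_scene(scene_spec(
      camera = camera, target_cover_fraction = 0,
      sunlit_leaf_fraction = 0.06, nontarget_yellow_flower_count = 6,
      seed = seed0 + j
    ))
  })
  names(scenes) <- sprintf("%s_dis%02d", camera$name, seq_len(n))
  scenes
}

# one full mining round at a given seed; used by the mining tests and the
# false-positive-reduction acceptance check
mining_round <- function(seed) {
  cam <- camera_profile("camA")
  fit <- small_model_for(cam, seed)
  mine <- distractor_scenes(cam, 6, seed + 100)
  report <- harvest_false_positives(fit$model, mine)
  m2 <- retrain_with_hard_negatives(fit$dataset, report, model_template = fit$model,
                                    seed = fit$seed + 2)$model
  held <- distractor_scenes(cam, 5, seed + 200)
  list(
    report = report,
    fp_model1 = harvest_false_positives(fit$model, held)$n_harvested,
    fp_model2 = harvest_false_positives(m2, held)$n_harvested,
    model1 = fit$model, model2 = m2, dataset = fit$dataset
  )
}

cached_mining_rounds <- function() {
  memo("mining_rounds", lapply(c(1000, 2000, 3000), mining_round))
}

# default-architecture model trained under the scaled-down study conditions:
# 60 scenes of 200 x 200 px, 2,500 tiles (2,000 in the training split)
cached_default_fit <- function() {
  memo("default_fit", {
    cam <- camera_profile("camA")
    corpus <- make_corpus(60, scene_spec(camera = cam),
                          length_range = c(10, 160), cover_range = c(0.15, 0.6),
                          seed = 4101)
    dataset <- build_dataset_from_corpus(corpus, n_per_class = 1250, seed = 4102)
    model <- build_network(30, train_config(epochs = 10), seed = 4103)
    model <- train_network(model, dataset, seed = 4104)
    list(corpus = corpus, dataset = dataset, model = model)
  })
}

two_camera_fits <- function() {
  memo("two_camera_fits", {
    cams <- list(
      camA = camera_profile("camA"),
      camB = camera_profile("camB", gain = c(0.55, 0.50, 0.90), offset = c(15, 20, 25))
    )
    fits <- list(
      camA = cached_small_fit(),
      camB = small_model_for(cams$camB, 22000)
    )
    tests <- lapply(cams, function(cam) {
      sd0 <- if (cam$name == "camA") 11000 else 22000
      pos <- lapply(1:3, function(j) {
        make_scene(scene_spec(camera = cam, target_cover_fraction = 1, seed = sd0 + 200 + j))
      })
      neg <- lapply(1:3, function(j) {
        make_scene(scene_spec(camera = cam, target_cover_fraction = 0,
                              sunlit_leaf_fraction = 0.03,
                              nontarget_yellow_flower_count = 3,
                              seed = sd0 + 300 + j))
      })
      names(pos) <- sprintf("%s_p%d", cam$name, 1:3)
      names(neg) <- sprintf("%s_n%d", cam$name, 1:3)
      build_test_set(pos, neg, n_tiles = 500, seed = sd0 + 4)
    })
    list(
      models = lapply(fits, `[[`, "model"),
      test_sets = tests
    )
  })
}

tiny_pipeline_config <- function() {
  pipeline_config(
    train = train_config(epochs = 2, batch_size = 64),
    conv_filters = c(8, 16), dense_units = 32,
    scene_width_px = 140, scene_height_px = 140,
    n_train_scenes = 8, n_mining_scenes = 2,
    n_test_pos = 2, n_test_neg = 2,
    n_per_class = 150, n_test_tiles = 100,
    seed = 77
  )
}

cached_tiny_runs <- function() {
  memo("tiny_runs", {
    root <- file.path(tempdir(), "tilecover-tiny-runs")
    r1 <- run_experiment(tiny_pipeline_config(), out_dir = root)
    r2 <- run_experiment(tiny_pipeline_config(), out_dir = root)
    list(r1 = r1, r2 = r2)
  })
}
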