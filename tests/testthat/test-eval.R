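test_that("confusion counts tally the four cells exactly", {
  cc <- confusion_counts(rep(1, 10), rep(1, 10))
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 10L, fn = 0L, fp = 0L, tn = 0L))
  cc2 <- confusion_counts(c(rep(0, 5), rep(1, 5)), c(rep(1, 5), rep(0, 5)))
  expect_equal(unlist(cc2[c("tp", "fn", "fp", "tn")]),
               c(tp = 0L, fn = 5L, fp = 5L, tn = 0L))
  set.seed(77)
  call <- rbinom(20, 1, 0.5); label <- rbinom(20, 1, 0.5)
  cc3 <- confusion_counts(call, label)
  tally <- table(factor(call, 0:1), factor(label, 0:1))
  expect_equal(cc3$tp, tally["1", "1"], ignore_attr = TRUE)
  expect_equal(cc3$fn, tally["0", "1"], ignore_attr = TRUE)
  expect_equal(cc3$fp, tally["1", "0"], ignore_attr = TRUE)
  expect_equal(cc3$tn, tally["0", "0"], ignore_attr = TRUE)
  expect_equal(cc3$tp + cc3$fn + cc3$fp + cc3$tn, 20L)
  expect_error(confusion_counts(1, c(1, 0)), "mismatch")
  expect_error(confusion_counts(c(2, 0), c(1, 0)), "binary")
})

test_that("metrics reproduce the worked confusion tables", {
  m <- classification_metrics(tibble::tibble(tp = 40, fn = 10, fp = 5, tn = 45))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 0.80)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$kappa, 0.70)

  perfect <- classification_metrics(tibble::tibble(tp = 50, fn = 0, fp = 0, tn = 50))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  chance <- classification_metrics(tibble::tibble(tp = 25, fn = 25, fp = 25, tn = 25))
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$kappa, 0)
})

test_that("metrics agree with independent implementations on random tables", {
  has_e1071 <- requireNamespace("e1071", quietly = TRUE)
  set.seed(2024)
  for (i in 1:200) {
    cts <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                   c("tp", "fn", "fp", "tn")))
    if (sum(unlist(cts)) == 0) cts$tp <- 1
    m <- classification_metrics(tibble::as_tibble(cts))
    o <- metrics_oracle(cts$tp, cts$fn, cts$fp, cts$tn)
    expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(m$recall, o$recall, tolerance = 1e-12)
    expect_equal(m$precision, o$precision, tolerance = 1e-12)
    expect_equal(m$kappa, o$kappa, tolerance = 1e-12)
    if (has_e1071 && !is.na(o$kappa)) {
      tab <- matrix(c(cts$tn, cts$fn, cts$fp, cts$tp), 2, 2)
      expect_equal(m$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-9)
    }
    if (!is.na(m$kappa)) {
      expect_gte(m$kappa, -1); expect_lte(m$kappa, 1)
    }
  }
})

test_that("kappa is 1 exactly when both classes are present and error-free", {
  set.seed(5)
  for (i in 1:50) {
    tp <- sample(1:20, 1); tn <- sample(1:20, 1)
    fp <- sample(0:3, 1); fn <- sample(0:3, 1)
    k <- classification_metrics(tibble::tibble(tp = tp, fn = fn, fp = fp, tn = tn))$kappa
    if (fp == 0 && fn == 0) expect_equal(k, 1) else expect_lt(k, 1)
  }
})

test_that("degenerate denominators are flagged, not propagated as NaN", {
  m <- classification_metrics(tibble::tibble(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(m$recall))
  expect_false(is.nan(m$accuracy))
  expect_true("recall" %in% m$undefined[[1]])
  expect_error(classification_metrics(tibble::tibble(tp = 0, fn = 0, fp = 0, tn = 0)),
               "empty")
})

test_that("the pure-cover test protocol draws a balanced seeded sample", {
  cam <- camera_profile("camA")
  pos <- lapply(1:2, function(j) {
    make_scene(scene_spec(camera = cam, target_cover_fraction = 1, seed = 600 + j))
  })
  neg <- lapply(1:2, function(j) {
    make_scene(scene_spec(camera = cam, target_cover_fraction = 0, seed = 650 + j))
  })
  ts <- build_test_set(pos, neg, n_tiles = 500, seed = 10)
  expect_equal(nrow(ts), 500L)
  expect_equal(sum(ts$label == 1), 250L)
  expect_equal(sum(ts$label == 0), 250L)
  expect_true(all(ts$split == "test"))

  again <- build_test_set(pos, neg, n_tiles = 500, seed = 10)
  expect_identical(ts, again)

  tiny <- build_test_set(pos[1], neg[1], n_tiles = 2, seed = 3)
  expect_equal(sum(tiny$label == 1), 1L)
  expect_equal(sum(tiny$label == 0), 1L)

  expect_error(build_test_set(pos, neg, n_tiles = 10000, seed = 1), "not enough")
})

test_that("transfer matrix cells equal direct evaluations", {
  fits <- two_camera_fits()
  one <- transfer_matrix(fits$models["camA"], fits$test_sets["camA"])
  expect_equal(nrow(one), 1L)
  direct <- evaluate_model(fits$models$camA, fits$test_sets$camA)
  expect_equal(one$kappa, direct$kappa)
  expect_equal(one$tp, direct$tp)
  # count conservation against the test-set composition
  expect_equal(one$tp + one$fn, sum(fits$test_sets$camA$label == 1))
  expect_equal(one$n, nrow(fits$test_sets$camA))

  # an error-free reference classifier gives an all-kappa-1 matrix
  # (distractor-free scenes, where the colour rule is exact)
  cam <- camera_profile("camA")
  clean_pos <- list(make_scene(scene_spec(camera = cam, target_cover_fraction = 1, seed = 710)))
  clean_neg <- list(make_scene(scene_spec(camera = cam, target_cover_fraction = 0, seed = 720)))
  clean <- build_test_set(clean_pos, clean_neg, n_tiles = 100, seed = 11)
  oracle_model <- function(tiles) color_threshold_oracle(tiles)
  tm <- transfer_matrix(list(a = oracle_model, b = oracle_model), list(clean = clean))
  expect_true(all(tm$kappa == 1))

  km <- kappa_matrix(transfer_matrix(fits$models, fits$test_sets))
  expect_equal(km$model_source, c("camA", "camB", "Average"))
  expect_equal(km$camA[3], mean(km$camA[1:2]))
  expect_s3_class(autoplot(transfer_matrix(fits$models, fits$test_sets)), "ggplot")
})
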