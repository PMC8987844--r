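test_that("size classes follow the S/M/L pixel bounds and partition [10, 300]", {
  expect_equal(
    classify_size(c(10, 50, 51, 100, 101, 300, 75)),
    c("S", "S", "M", "M", "L", "L", "M")
  )
  expect_equal(classify_size(c(9, 301)), c("OUT_OF_RANGE", "OUT_OF_RANGE"))
  expect_error(classify_size(0), "positive")
  expect_error(classify_size(-5), "positive")
  # every in-range length falls in exactly one class
  cls <- classify_size(10:300)
  expect_true(all(cls %in% c("S", "M", "L")))
  expect_equal(sum(cls == "S"), 41L)   # 10..50
  expect_equal(sum(cls == "M"), 50L)   # 51..100
  expect_equal(sum(cls == "L"), 200L)  # 101..300
})

test_that("green fraction implements the foliage predicate exactly", {
  expect_equal(green_fraction(uniform_image(c(255, 255, 0))), 0)
  expect_equal(green_fraction(uniform_image(c(0, 160, 0))), 1)
  half <- uniform_image(c(255, 255, 0))
  half[, 1:15, 1] <- 0; half[, 1:15, 2] <- 160; half[, 1:15, 3] <- 0
  expect_equal(green_fraction(half), 0.5)
  # brute-force pixel count on a random tile
  set.seed(31)
  tile <- random_image(12, 12, seed = 31)
  px <- matrix(aperm(tile, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  manual <- mean(hsv[1, ] * 360 >= 70 & hsv[1, ] * 360 <= 170 &
                   hsv[2, ] >= 0.25 & hsv[3, ] >= 0.15)
  expect_equal(green_fraction(tile), manual)
})

test_that("dataset construction labels, filters and splits tiles", {
  pos <- list(p1 = uniform_image(c(255, 255, 0), 60))
  neg <- list(n1 = uniform_image(c(0, 160, 0), 60))
  ds <- build_tile_dataset(pos, neg, chop_config(), split_fraction = 0.8, seed = 1)
  expect_equal(nrow(ds), 18L)
  expect_equal(sum(ds$label == 1), 9L)
  expect_equal(sum(ds$label == 0), 9L)
  expect_setequal(unique(ds$split), c("train", "validation"))
  # split is disjoint by tile identity and stratified by label
  key <- paste(ds$source_id, ds$grid_row, ds$grid_col)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(sum(ds$label == 1 & ds$split == "train"), 7L)

  # a fully green "positive" source fails the purity rule entirely
  expect_error(
    build_tile_dataset(list(p = uniform_image(c(0, 160, 0), 60)), neg, seed = 1),
    "purity"
  )
})

test_that("purity filtering is monotone in the threshold", {
  set.seed(8)
  sc <- make_scene(scene_spec(target_cover_fraction = 0.5, seed = 21))
  tiles <- scene_tiles(sc)
  pos <- tiles[tiles$label == 1, ]
  gf <- vapply(pos$pixels, green_fraction, numeric(1))
  kept <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th) sum(gf < th), integer(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("size-mixed sampling keeps all three classes represented", {
  imgs <- list(
    s1 = uniform_image(c(255, 255, 0), 60),
    s2 = uniform_image(c(250, 240, 20), 60),
    s3 = uniform_image(c(240, 230, 40), 60)
  )
  pos <- tibble::tibble(
    source_id = names(imgs), image = imgs,
    reference_length_px = c(30, 75, 150)
  )
  neg <- list(n1 = uniform_image(c(0, 160, 0), 60))
  ds <- build_tile_dataset(pos, neg, mix_sizes = TRUE, n_per_class = 6, seed = 2)
  expect_equal(sum(ds$label == 1), 6L)
  expect_setequal(unique(ds$size_class[ds$label == 1]), c("S", "M", "L"))
})

test_that("augmentation rescales, preserves labels and is seed-reproducible", {
  set <- separable_tile_set(10, seed = 3)
  ident <- augment_config(0, 0, FALSE, 0)
  st <- augment_stream(set, ident, seed = 5)
  b <- st$next_batch(8)
  expect_equal(dim(b$x), c(30, 30, 3, 8))
  expect_true(all(b$x >= 0 & b$x <= 1))
  # identity config: emitted tiles equal source tiles / 255
  first_of <- function(i) set$pixels[[i]] / 255
  set.seed(5); idx <- sample.int(nrow(set), 8, replace = TRUE)
  for (i in seq_len(8)) {
    expect_equal(b$x[, , , i], first_of(idx[i])[, , ], ignore_attr = TRUE)
    expect_equal(b$label[i], set$label[idx[i]])
  }

  cfg <- augment_config()
  s1 <- augment_stream(set, cfg, seed = 9)
  s2 <- augment_stream(set, cfg, seed = 9)
  b1 <- lapply(1:3, function(i) s1$next_batch(16))
  b2 <- lapply(1:3, function(i) s2$next_batch(16))
  expect_identical(b1, b2)
  expect_true(all(vapply(b1, function(b) all(b$x >= 0 & b$x <= 1), logical(1))))

  # the stream's private RNG does not disturb the session RNG
  set.seed(123); before <- runif(3)
  s3 <- augment_stream(set, cfg, seed = 1)
  set.seed(123); invisible(s3$next_batch(4)); after <- runif(3)
  expect_identical(before, after)
})
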