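test_that("chop configuration validates tile size, overlap and stride", {
  cfg <- chop_config()
  expect_equal(cfg$tile_size_px, 30L)
  expect_equal(cfg$stride_px, 15L)
  expect_equal(chop_config(20, 0)$stride_px, 20L)
  expect_error(chop_config(25, 0.5), "stride")     # 12.5 px is not integral
  expect_error(chop_config(1, 0), ">= 2")
  expect_error(chop_config(30, 1), "\\[0, 1\\)")
})

test_that("grid geometry matches the worked examples", {
  g <- tile_grid(60, 60, chop_config())
  expect_equal(c(g$n_rows, g$n_cols), c(3L, 3L))
  g1 <- tile_grid(30, 30, chop_config())
  expect_equal(c(g1$n_rows, g1$n_cols), c(1L, 1L))
  # full-frame mirrorless capture, 30 px tiles at 50% overlap
  g2 <- tile_grid(5184, 3888, chop_config())
  expect_equal(g2$n_cols, 344L)
  expect_equal(g2$n_rows, 258L)
  expect_equal(g2$n_cols * g2$n_rows, 88752L)
})

test_that("chopping equals the brute-force position enumeration", {
  img <- random_image(60, 60, seed = 101)
  tiles <- chop_image(img, chop_config())
  expect_equal(nrow(tiles), 9L)
  expect_identical(tiles$pixels, brute_chop(img, 30, 0.5))

  one <- chop_image(random_image(30, 30, seed = 5), chop_config())
  expect_equal(nrow(one), 1L)
  expect_identical(one$pixels[[1]][, , ], random_image(30, 30, seed = 5)[, , ])

  set.seed(42)
  for (i in 1:12) {
    h <- sample(10:120, 1); w <- sample(10:120, 1)
    ov <- sample(c(0, 0.5), 1)
    t <- sample(c(10, 16, 30), 1)
    img <- random_image(h, w, seed = 1e5 + i)
    tiles <- suppressWarnings(chop_image(img, chop_config(t, ov)))
    oracle <- brute_chop(img, t, ov)
    expect_equal(nrow(tiles), length(oracle))
    expect_identical(tiles$pixels, oracle)
  }
})

test_that("tiles arrive row-major with 0-based indices and exact crops", {
  img <- random_image(45, 60, seed = 7)
  tiles <- chop_image(img, chop_config(30, 0.5), source_id = "s")
  grid <- chop_grid(tiles)
  expect_equal(grid$n_rows, 2L)
  expect_equal(grid$n_cols, 3L)
  expect_equal(tiles$grid_row, rep(0:1, each = 3))
  expect_equal(tiles$grid_col, rep(0:2, times = 2))
  b <- tile_bounds(grid, 1, 2)
  expect_equal(unname(b), c(30L, 15L, 60L, 45L))
  expect_identical(
    tiles$pixels[[6]],
    img[(b["y0"] + 1):b["y1"], (b["x0"] + 1):b["x1"], , drop = FALSE]
  )
  expect_equal(unname(tile_bounds(grid, 0, 0)), c(0L, 0L, 30L, 30L))
  expect_error(tile_bounds(grid, grid$n_rows, 0), "outside")
  expect_error(tile_bounds(grid, 0, -1), "outside")
})

test_that("images smaller than a tile give an empty grid with a warning", {
  img <- random_image(20, 50, seed = 3)
  expect_warning(tiles <- chop_image(img, chop_config()), "smaller")
  expect_equal(nrow(tiles), 0L)
  expect_equal(chop_grid(tiles)$n_rows, 0L)
})

test_that("50% overlap covers every interior pixel by 1 to 4 tiles", {
  for (sz in list(c(60, 60), c(75, 45), c(90, 120))) {
    g <- tile_grid(sz[2], sz[1], chop_config())
    s <- g$stride_px; t <- g$tile_size_px
    cover <- matrix(0L, sz[1], sz[2])
    for (r in 0:(g$n_rows - 1)) for (co in 0:(g$n_cols - 1)) {
      cover[r * s + seq_len(t), co * s + seq_len(t)] <-
        cover[r * s + seq_len(t), co * s + seq_len(t)] + 1L
    }
    ch <- (g$n_rows - 1) * s + t
    cw <- (g$n_cols - 1) * s + t
    covered <- cover[seq_len(ch), seq_len(cw)]
    expect_true(all(covered >= 1L))
    expect_true(all(covered <= 4L))
    if (ch < sz[1]) expect_true(all(cover[(ch + 1):sz[1], ] == 0L))
  }
})

test_that("chopping is deterministic and tile files round-trip", {
  img <- random_image(60, 60, seed = 9)
  a <- chop_image(img, chop_config(), source_id = "x")
  b <- chop_image(img, chop_config(), source_id = "x")
  expect_identical(a, b)

  dir <- withr::local_tempdir()
  write_tiles(a, dir)
  expect_true(file.exists(file.path(dir, "x_r0_c0.png")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_rows, 3L)
  back <- read_image(file.path(dir, "x_r1_c2.png"))
  expect_equal(back, a$pixels[[6]], ignore_attr = TRUE)
})
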