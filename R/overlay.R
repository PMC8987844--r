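#' Fuse per-tile probabilities onto the stride-cell lattice
#'
#' Under 50% overlap every stride-sized cell of the image is covered by up
#' to four tiles. Overlapping predictions are fused per cell as the mean
#' probability over all tiles whose footprint contains the cell, then
#' thresholded into a positive/negative call. The fraction of positive
#' cells estimates the target's cover in the image.
#'
#' @param grid a [tile_grid()].
#' @param probabilities numeric vector, one probability per tile in
#'   row-major grid order (as produced by [chop_image()] +
#'   [predict_tiles()]).
#' @param threshold cell call cut-off on the mean probability.
#' @return a `coverage_map`: list with `grid`, `cell_px` (cell side =
#'   stride), `prob` and `call` matrices on the cell lattice, and
#'   `positive_fraction`.
#' @export
aggregate_cells <- function(grid, probabilities, threshold = 0.5) {
  stopifnot(inherits(grid, "tile_grid"))
  n_tiles <- grid$n_rows * grid$n_cols
  if (length(probabilities) != n_tiles) {
    abort(sprintf("expected %d probabilities (one per tile), got %d",
                  n_tiles, length(probabilities)))
  }
  if (n_tiles == 0) abort("empty grid")
  if (grid$tile_size_px %% grid$stride_px != 0) {
    abort("cell aggregation requires the tile size to be a multiple of the stride")
  }
  k <- grid$tile_size_px %/% grid$stride_px
  # tile (r, c) covers cell rows r..r+k-1, cols c..c+k-1
  P <- matrix(probabilities, grid$n_rows, grid$n_cols, byrow = TRUE)
  nr <- grid$n_rows + k - 1L
  nc <- grid$n_cols + k - 1L
  S <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in 0:(k - 1)) {
    for (dc in 0:(k - 1)) {
      rows <- dr + seq_len(grid$n_rows)
      cols <- dc + seq_len(grid$n_cols)
      S[rows, cols] <- S[rows, cols] + P
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
  }
  prob <- S / cnt
  call <- prob >= threshold
  structure(
    list(
      grid = grid, cell_px = grid$stride_px, threshold = threshold,
      prob = prob, call = call,
      positive_fraction = mean(call)
    ),
    class = "coverage_map"
  )
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf(
    "<coverage_map> %d x %d cells of %d px, positive fraction %.3f\n",
    nrow(x$call), ncol(x$call), x$cell_px, x$positive_fraction
  ))
  invisible(x)
}

#' Chop, classify and fuse an image into a coverage map
#'
#' @param model a trained `tile_cnn` (or classifier function).
#' @param image an `H x W x 3` array or a [make_scene()] scene.
#' @param chop a [chop_config()].
#' @param threshold cell call cut-off.
#' @return a `coverage_map` (see [aggregate_cells()]).
#' @export
estimate_coverage <- function(model, image, chop = chop_config(), threshold = 0.5) {
  if (inherits(image, "scene")) image <- image$image
  tiles <- chop_image(image, chop)
  pred <- predict_tiles(model, tiles)
  aggregate_cells(chop_grid(tiles), pred$probability, threshold = threshold)
}

#' Render the red/green detection mosaic over an image
#'
#' Cells called positive are tinted red, negative cells green,
#' alpha-blended over the source image. Pixels right/below the last full
#' tile footprint are left untinted.
#'
#' @param image the source `H x W x 3` array (intensities 0–255) or scene.
#' @param map a `coverage_map` computed on the same image.
#' @param alpha blend weight of the tint in `[0, 1]` (0 returns the image
#'   unchanged).
#' @return an `H x W x 3` array, intensities in `[0, 255]`.
#' @export
render_overlay <- function(image, map, alpha = 0.4) {
  if (inherits(image, "scene")) image <- image$image
  check_image(image)
  stopifnot(inherits(map, "coverage_map"), alpha >= 0, alpha <= 1)
  g <- map$grid
  if (dim(image)[1] != g$image_height_px || dim(image)[2] != g$image_width_px) {
    abort(sprintf(
      "image is %d x %d px but the coverage map was built for %d x %d",
      dim(image)[2], dim(image)[1], g$image_width_px, g$image_height_px
    ))
  }
  s <- map$cell_px
  cov_h <- nrow(map$call) * s
  cov_w <- ncol(map$call) * s
  pos <- kronecker(map$call, matrix(TRUE, s, s))
  out <- image
  region <- function(ch) out[seq_len(cov_h), seq_len(cov_w), ch]
  tint <- list(
    r = ifelse(pos, 255, 0),
    g = ifelse(pos, 0, 255),
    b = matrix(0, cov_h, cov_w)
  )
  for (ch in 1:3) {
    out[seq_len(cov_h), seq_len(cov_w), ch] <-
      (1 - alpha) * region(ch) + alpha * tint[[ch]]
  }
  out
}

#' Coverage summary as JSON-ready list
#'
#' @param map a `coverage_map`.
#' @param source_id identifier recorded in the summary.
#' @return list with `source_id`, `n_cells`, `n_positive`,
#'   `positive_fraction`.
#' @export
coverage_summary <- function(map, source_id = "image") {
  stopifnot(inherits(map, "coverage_map"))
  list(
    source_id = source_id,
    n_cells = length(map$call),
    n_positive = sum(map$call),
    positive_fraction = map$positive_fraction
  )
}

#' @export
autoplot.coverage_map <- function(object, what = c("call", "prob"), ...) {
  what <- match.arg(what)
  m <- if (what == "call") object$call * 1 else object$prob
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "forestgreen", high = "firebrick",
                                 limits = c(0, 1), name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
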