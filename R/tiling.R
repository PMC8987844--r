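#' Tiling configuration for the chopped-picture method
#'
#' The chopped-picture method cuts an image into small square tiles that
#' overlap their neighbours, so that amorphous vegetation cover can be
#' classified tile by tile. The defaults — 30-pixel tiles with 50% overlap
#' in both directions — are the standard settings for goldenrod inflorescence
#' mapping.
#'
#' @param tile_size_px side of the square tile in pixels (>= 2).
#' @param overlap_fraction fraction of tile side shared with the next tile,
#'   in `[0, 1)`. The stride between tile origins is
#'   `tile_size_px * (1 - overlap_fraction)` and must come out a whole
#'   positive number of pixels.
#' @return an object of class `chop_config` with fields `tile_size_px`,
#'   `overlap_fraction`, `stride_px`.
#' @examples
#' chop_config()                # 30 px tiles, 50% overlap, stride 15
#' chop_config(20, 0)           # disjoint 20 px tiles
#' @export
chop_config <- function(tile_size_px = 30, overlap_fraction = 0.5) {
  if (!is_count(tile_size_px) || tile_size_px < 2) {
    abort("`tile_size_px` must be a whole number >= 2")
  }
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1 ||
      overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must lie in [0, 1)")
  }
  stride <- tile_size_px * (1 - overlap_fraction)
  if (abs(stride - round(stride)) > 1e-8 || round(stride) < 1) {
    abort(sprintf(
      "tile_size_px * (1 - overlap_fraction) = %.3f is not a positive whole stride",
      stride
    ))
  }
  structure(
    list(
      tile_size_px = as.integer(tile_size_px),
      overlap_fraction = overlap_fraction,
      stride_px = as.integer(round(stride))
    ),
    class = "chop_config"
  )
}

#' @export
print.chop_config <- function(x, ...) {
  cat(sprintf(
    "<chop_config> tile %d px, overlap %.0f%%, stride %d px\n",
    x$tile_size_px, 100 * x$overlap_fraction, x$stride_px
  ))
  invisible(x)
}

#' Tile grid geometry for an image
#'
#' Computes how many full tiles fit into an image under a tiling
#' configuration. Tiles are indexed 0-based and row-major: tile `(r, c)` has
#' its top-left pixel at `(x, y) = (c * stride, r * stride)`, rows indexing
#' image height. Only positions where the whole tile lies inside the image
#' are counted; remainder pixels at the right/bottom edge are dropped.
#'
#' @param image_width_px,image_height_px image dimensions in pixels.
#' @param config a [chop_config()].
#' @return an object of class `tile_grid` with fields `image_width_px`,
#'   `image_height_px`, `tile_size_px`, `stride_px`, `n_rows`, `n_cols`.
#' @examples
#' tile_grid(60, 60, chop_config())        # 3 x 3 grid
#' tile_grid(5184, 3888, chop_config())    # 344 x 258 columns x rows
#' @export
tile_grid <- function(image_width_px, image_height_px, config = chop_config()) {
  stopifnot(inherits(config, "chop_config"))
  if (!is_count(image_width_px) || !is_count(image_height_px)) {
    abort("image dimensions must be positive whole numbers")
  }
  t <- config$tile_size_px
  s <- config$stride_px
  n_cols <- if (image_width_px >= t) (image_width_px - t) %/% s + 1L else 0L
  n_rows <- if (image_height_px >= t) (image_height_px - t) %/% s + 1L else 0L
  structure(
    list(
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      tile_size_px = t,
      stride_px = s,
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols)
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(
    "<tile_grid> %d x %d px image, tile %d stride %d: %d rows x %d cols = %d tiles\n",
    x$image_width_px, x$image_height_px, x$tile_size_px, x$stride_px,
    x$n_rows, x$n_cols, x$n_rows * x$n_cols
  ))
  invisible(x)
}

#' Pixel bounds of one tile
#'
#' @param grid a [tile_grid()].
#' @param row,col 0-based tile indices (`row` along height).
#' @return integer vector `c(x0, y0, x1, y1)`, a half-open rectangle:
#'   the tile covers pixel columns `[x0, x1)` and rows `[y0, y1)`.
#' @export
tile_bounds <- function(grid, row, col) {
  stopifnot(inherits(grid, "tile_grid"))
  if (!is.numeric(row) || !is.numeric(col) ||
      row < 0 || row >= grid$n_rows || col < 0 || col >= grid$n_cols) {
    abort(sprintf(
      "tile index (%s, %s) outside grid %d x %d",
      toString(row), toString(col), grid$n_rows, grid$n_cols
    ))
  }
  x0 <- as.integer(col) * grid$stride_px
  y0 <- as.integer(row) * grid$stride_px
  c(x0 = x0, y0 = y0, x1 = x0 + grid$tile_size_px, y1 = y0 + grid$tile_size_px)
}

#' Chop an image into overlapping square tiles
#'
#' Extracts every full tile of the grid in row-major order (row 0 left to
#' right, then row 1, ...). Each tile's pixels are an exact crop of the
#' input; nothing is padded or interpolated.
#'
#' @param image `H x W x 3` numeric array, intensities in `[0, 255]`.
#' @param config a [chop_config()].
#' @param source_id identifier recorded with every tile (e.g. camera or
#'   file name).
#' @return a tibble with one row per tile and columns `source_id`,
#'   `grid_row`, `grid_col` (0-based) and `pixels` (list column of
#'   `tile x tile x 3` arrays). The [tile_grid()] is attached as attribute
#'   `"grid"` (see [chop_grid()]). An image smaller than the tile size in
#'   either dimension yields zero rows with a warning.
#' @examples
#' img <- array(runif(60 * 60 * 3, 0, 255), c(60, 60, 3))
#' tiles <- chop_image(img, chop_config())
#' nrow(tiles)        # 9
#' chop_grid(tiles)
#' @export
chop_image <- function(image, config = chop_config(), source_id = "image") {
  check_image(image)
  grid <- tile_grid(dim(image)[2], dim(image)[1], config)
  if (grid$n_rows == 0L || grid$n_cols == 0L) {
    warn(sprintf(
      "image %s (%d x %d px) is smaller than the %d px tile: empty grid",
      source_id, grid$image_width_px, grid$image_height_px, grid$tile_size_px
    ))
    out <- tibble(
      source_id = character(), grid_row = integer(), grid_col = integer(),
      pixels = list()
    )
    attr(out, "grid") <- grid
    return(out)
  }
  t <- grid$tile_size_px
  s <- grid$stride_px
  idx <- expand.grid(grid_col = 0:(grid$n_cols - 1), grid_row = 0:(grid$n_rows - 1))
  pixels <- purrr::map2(idx$grid_row, idx$grid_col, function(r, co) {
    image[r * s + seq_len(t), co * s + seq_len(t), , drop = FALSE]
  })
  out <- tibble(
    source_id = source_id,
    grid_row = as.integer(idx$grid_row),
    grid_col = as.integer(idx$grid_col),
    pixels = pixels
  )
  attr(out, "grid") <- grid
  out
}

#' Grid geometry attached to a chopped-tile tibble
#'
#' @param tiles the result of [chop_image()].
#' @return the [tile_grid()] the tiles were cut on.
#' @export
chop_grid <- function(tiles) {
  g <- attr(tiles, "grid")
  if (is.null(g)) abort("`tiles` carries no grid attribute; was it made by chop_image()?")
  g
}

#' Write chopped tiles and their grid manifest to a directory
#'
#' Tiles are written as `\{source_id\}_r\{row\}_c\{col\}.png` next to a
#' `manifest.json` recording the grid geometry.
#'
#' @param tiles result of [chop_image()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- chop_grid(tiles)
  purrr::pwalk(
    list(tiles$source_id, tiles$grid_row, tiles$grid_col, tiles$pixels),
    function(sid, r, co, px) {
      write_image(px, file.path(dir, sprintf("%s_r%d_c%d.png", sid, r, co)))
    }
  )
  jsonlite::write_json(
    unclass(grid), file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
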