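#' Size class of an inflorescence from its reference-length in pixels
#'
#' Training imagery is stratified by the apparent size of the target: the
#' pixel length of the primary inflorescence branch (the branch splitting
#' off the main inflorescence axis) measured on the image. Classes are
#' S = 10–50 px, M = 51–100 px, L = 101–300 px; lengths outside `[10, 300]`
#' are flagged `OUT_OF_RANGE`.
#'
#' @param reference_length_px positive integer vector of measured lengths.
#' @return character vector of `"S"`, `"M"`, `"L"` or `"OUT_OF_RANGE"`.
#' @examples
#' classify_size(c(10, 50, 51, 100, 101, 300, 9, 301))
#' @export
classify_size <- function(reference_length_px) {
  if (!is.numeric(reference_length_px) || length(reference_length_px) == 0 ||
      anyNA(reference_length_px) || any(reference_length_px < 1) ||
      any(abs(reference_length_px - round(reference_length_px)) > 1e-8)) {
    abort("`reference_length_px` must be positive whole numbers")
  }
  x <- round(reference_length_px)
  dplyr::case_when(
    x >= 10 & x <= 50 ~ "S",
    x >= 51 & x <= 100 ~ "M",
    x >= 101 & x <= 300 ~ "L",
    TRUE ~ "OUT_OF_RANGE"
  )
}

#' Fraction of green-foliage pixels in a tile
#'
#' Positive training tiles must be mostly flower: tiles whose green-leaf
#' share reaches the purity threshold (default 20%) are discarded. The
#' original curation was manual; this operational predicate calls a pixel
#' "green foliage" when its HSV hue falls in `[70, 170]` degrees with
#' saturation >= 0.25 and value >= 0.15. All three cut-offs are arguments.
#'
#' @param tile `H x W x 3` array, intensities in `[0, 255]`.
#' @param hue_range green hue window in degrees.
#' @param min_saturation,min_value HSV saturation/value floors.
#' @return the fraction of pixels matching the predicate, in `[0, 1]`.
#' @export
green_fraction <- function(tile, hue_range = c(70, 170),
                           min_saturation = 0.25, min_value = 0.15) {
  check_image(tile, "tile")
  px <- matrix(aperm(tile, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  green <- hue >= hue_range[1] & hue <= hue_range[2] &
    hsv[2, ] >= min_saturation & hsv[3, ] >= min_value
  mean(green)
}

# Coerce positive/negative source inputs to tibble(source_id, image, [reference_length_px]).
# Accepts a tibble/data.frame with those columns, a named list of arrays, or
# a character vector of image paths.
as_source_tibble <- function(x, arg) {
  if (is.data.frame(x)) {
    if (!all(c("source_id", "image") %in% names(x))) {
      abort(sprintf("`%s` needs columns `source_id` and `image`", arg))
    }
    return(as_tibble(x))
  }
  if (is.character(x)) {
    ids <- tools::file_path_sans_ext(basename(x))
    return(tibble(source_id = ids, image = purrr::map(x, read_image)))
  }
  if (is.list(x)) {
    ids <- names(x)
    if (is.null(ids) || any(ids == "")) ids <- sprintf("%s_%02d", arg, seq_along(x))
    return(tibble(source_id = ids, image = x))
  }
  abort(sprintf("`%s` must be a tibble, named list of arrays, or paths", arg))
}

#' Build a labeled, size-stratified tile dataset
#'
#' Chops positive-source images (target plant in flower) and negative-source
#' images (no target) into tiles, labels them 1/0, removes positive tiles
#' that fail the green-foliage purity rule, optionally balances positives
#' across the S/M/L size classes, and assigns a seeded train/validation
#' split stratified by label.
#'
#' @param positives,negatives image sources: a tibble with columns
#'   `source_id`, `image` (list of `H x W x 3` arrays) and, for positives,
#'   optionally `reference_length_px`; or a named list of arrays; or a
#'   character vector of image paths.
#' @param chop a [chop_config()].
#' @param purity_threshold positive tiles with [green_fraction()] at or
#'   above this value are excluded (default 0.2).
#' @param mix_sizes when `TRUE` and size classes are known, positive
#'   sampling is stratified so every available size class is represented.
#' @param n_per_class optional cap on tiles kept per label class (drawn at
#'   random under `seed`).
#' @param split_fraction fraction of each label class tagged `train`; the
#'   rest are `validation`.
#' @param seed RNG seed for sampling and the split.
#' @return a tibble of class `tile_set` with columns `source_id`,
#'   `grid_row`, `grid_col`, `pixels`, `label` (integer 0/1), `size_class`
#'   (`NA` for negatives), `split`.
#' @export
build_tile_dataset <- function(positives, negatives, chop = chop_config(),
                               purity_threshold = 0.2, mix_sizes = TRUE,
                               n_per_class = NULL, split_fraction = 0.8,
                               seed = NULL) {
  pos <- as_source_tibble(positives, "positives")
  neg <- as_source_tibble(negatives, "negatives")
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("need at least one positive and one negative source image")
  }
  maybe_seed(seed)

  chop_all <- function(src) {
    purrr::map2(src$image, src$source_id, chop_image, config = chop) |>
      dplyr::bind_rows()
  }
  pos_tiles <- chop_all(pos)
  neg_tiles <- chop_all(neg)

  if ("reference_length_px" %in% names(pos)) {
    size_by_src <- stats::setNames(classify_size(pos$reference_length_px), pos$source_id)
    pos_tiles$size_class <- unname(size_by_src[pos_tiles$source_id])
  } else {
    pos_tiles$size_class <- NA_character_
  }
  neg_tiles$size_class <- NA_character_

  keep <- purrr::map_dbl(pos_tiles$pixels, green_fraction) < purity_threshold
  pos_tiles <- pos_tiles[keep, ]
  if (nrow(pos_tiles) == 0) {
    abort(sprintf(
      "positive class is empty after the <%d%% green purity filter", round(100 * purity_threshold)
    ))
  }
  if (nrow(neg_tiles) == 0) abort("negative class is empty")

  assemble_tile_set(pos_tiles, neg_tiles, mix_sizes = mix_sizes,
                    n_per_class = n_per_class, split_fraction = split_fraction)
}

# shared tail of dataset construction: per-class (optionally size-stratified)
# sampling, labeling, and the seeded train/validation split
assemble_tile_set <- function(pos_tiles, neg_tiles, mix_sizes = TRUE,
                              n_per_class = NULL, split_fraction = 0.8) {
  sample_class <- function(tiles, n, stratify_col = NULL) {
    if (is.null(n) || n >= nrow(tiles)) return(tiles)
    if (!is.null(stratify_col) && !all(is.na(tiles[[stratify_col]]))) {
      # equal per-class quotas (remainder spread over the first classes) so
      # every available size class stays represented
      groups <- split(seq_len(nrow(tiles)), tiles[[stratify_col]])
      quota <- rep(n %/% length(groups), length(groups))
      extra <- n - sum(quota)
      if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
      take <- unlist(purrr::map2(groups, quota, function(ix, q) {
        sample(ix, min(q, length(ix)))
      }), use.names = FALSE)
      left <- setdiff(seq_len(nrow(tiles)), take)
      short <- n - length(take)
      if (short > 0 && length(left) > 0) take <- c(take, sample(left, min(short, length(left))))
      return(tiles[sort(take), ])
    }
    dplyr::slice_sample(tiles, n = min(n, nrow(tiles)))
  }
  pos_tiles <- sample_class(pos_tiles, n_per_class, if (mix_sizes) "size_class" else NULL)
  neg_tiles <- sample_class(neg_tiles, n_per_class)

  pos_tiles$label <- 1L
  neg_tiles$label <- 0L
  all_tiles <- dplyr::bind_rows(pos_tiles, neg_tiles)

  # stratified-by-label split
  all_tiles <- all_tiles |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(split = {
      n <- dplyr::n()
      n_train <- max(1L, round(split_fraction * n))
      if (n_train >= n && n > 1) n_train <- n - 1L
      sp <- rep("validation", n)
      sp[sample.int(n, n_train)] <- "train"
      sp
    }) |>
    dplyr::ungroup()
  class(all_tiles) <- c("tile_set", class(all_tiles))
  all_tiles
}

#' Build a training dataset from a synthetic corpus
#'
#' Like [build_tile_dataset()], but tile labels come from each scene's
#' ground-truth mask (tile positive when mostly covered by target) instead
#' of from pure positive/negative source directories. The green-foliage
#' purity rule is still applied to positives.
#'
#' @param corpus a [make_corpus()] manifest.
#' @param chop a [chop_config()].
#' @param truth_threshold masked-fraction cut-off for a positive tile.
#' @inheritParams build_tile_dataset
#' @return a `tile_set` tibble (see [build_tile_dataset()]).
#' @export
build_dataset_from_corpus <- function(corpus, chop = chop_config(),
                                      truth_threshold = 0.5,
                                      purity_threshold = 0.2, mix_sizes = TRUE,
                                      n_per_class = NULL, split_fraction = 0.8,
                                      seed = NULL) {
  maybe_seed(seed)
  tiles <- corpus_tiles(corpus, chop, truth_threshold)
  pos_tiles <- tiles[tiles$label == 1L, ]
  neg_tiles <- tiles[tiles$label == 0L, ]
  keep <- purrr::map_dbl(pos_tiles$pixels, green_fraction) < purity_threshold
  pos_tiles <- pos_tiles[keep, ]
  if (nrow(pos_tiles) == 0) {
    abort("positive class is empty after the green purity filter")
  }
  if (nrow(neg_tiles) == 0) abort("negative class is empty")
  assemble_tile_set(pos_tiles, neg_tiles, mix_sizes = mix_sizes,
                    n_per_class = n_per_class, split_fraction = split_fraction)
}

#' Augmentation settings for training tiles
#'
#' Training tiles are randomly shifted, flipped and zoomed before each
#' epoch, and intensities rescaled from `[0, 255]` to `[0, 1]` by dividing
#' by 255. Shift/zoom magnitudes are fractions of the tile side; edge gaps
#' left by a transform are filled by nearest-pixel replication.
#'
#' @param width_shift_range,height_shift_range maximum horizontal/vertical
#'   shift as a fraction of the tile side, in `[0, 1)`.
#' @param horizontal_flip randomly mirror tiles left-right.
#' @param zoom_range zoom factor drawn from `[1 - zoom_range, 1 + zoom_range]`.
#' @param rescale_divisor intensity divisor (255 maps `[0,255]` to `[0,1]`).
#' @return an `augment_config` object.
#' @export
augment_config <- function(width_shift_range = 0.1, height_shift_range = 0.1,
                           horizontal_flip = TRUE, zoom_range = 0.2,
                           rescale_divisor = 255) {
  for (v in c(width_shift_range, height_shift_range, zoom_range)) {
    if (!is.numeric(v) || v < 0 || v >= 1) abort("shift/zoom ranges must lie in [0, 1)")
  }
  structure(
    list(
      width_shift_range = width_shift_range,
      height_shift_range = height_shift_range,
      horizontal_flip = isTRUE(horizontal_flip),
      zoom_range = zoom_range,
      rescale_divisor = rescale_divisor
    ),
    class = "augment_config"
  )
}

# Apply one sampled shift/flip/zoom to a raw 0-255 tile (nearest-neighbour
# resampling, edge replication). Returns a tile on the same intensity scale.
augment_tile <- function(tile, dx, dy, zoom, flip) {
  h <- dim(tile)[1]; w <- dim(tile)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- clamp(round((seq_len(h) - cy) / zoom + cy - dy), 1, h)
  xs <- clamp(round((seq_len(w) - cx) / zoom + cx - dx), 1, w)
  if (flip) xs <- rev(xs)
  tile[ys, xs, , drop = FALSE]
}

#' Infinite seeded stream of augmented training tiles
#'
#' Returns a generator over a tile set: each call to `$next_batch(n)` draws
#' `n` tiles (with replacement) from the set, applies a fresh random
#' shift/flip/zoom to each, rescales intensities to `[0, 1]`, and returns
#' them with their labels. The stream owns an isolated RNG, so two streams
#' built with the same seed emit identical sequences regardless of what the
#' caller does with the global RNG.
#'
#' @param set a `tile_set` (or any tibble with `pixels` and `label`).
#' @param config an [augment_config()].
#' @param seed integer seed for the stream's private RNG.
#' @return a `tile_stream`: list with `$next_batch(n)` returning
#'   `list(x = tile x tile x 3 x n array in [0,1], label = integer vector)`,
#'   plus `$config` and `$n_source`.
#' @export
augment_stream <- function(set, config = augment_config(), seed = 1) {
  if (nrow(set) == 0) abort("cannot stream from an empty tile set")
  stopifnot(inherits(config, "augment_config"))
  rng <- new_rng_stream(seed)
  tiles <- set$pixels
  labels <- as.integer(set$label)
  t_px <- dim(tiles[[1]])[1]
  nb <- function(n) {
    rng({
      idx <- sample.int(length(tiles), n, replace = TRUE)
      dxs <- runif(n, -config$width_shift_range, config$width_shift_range) * t_px
      dys <- runif(n, -config$height_shift_range, config$height_shift_range) * t_px
      zooms <- runif(n, 1 - config$zoom_range, 1 + config$zoom_range)
      flips <- if (config$horizontal_flip) runif(n) < 0.5 else rep(FALSE, n)
      x <- array(0, c(t_px, t_px, 3, n))
      for (i in seq_len(n)) {
        x[, , , i] <- augment_tile(tiles[[idx[i]]], dxs[i], dys[i], zooms[i], flips[i])
      }
      list(x = x / config$rescale_divisor, label = labels[idx])
    })
  }
  structure(
    list(next_batch = nb, config = config, n_source = length(tiles)),
    class = "tile_stream"
  )
}

# Stack a tile set (or list of tiles) into an (t*t*3) x N matrix of
# normalized intensities, the layout the CNN engine consumes.
tiles_to_matrix <- function(tiles, rescale_divisor = 255) {
  if (is.data.frame(tiles)) tiles <- tiles$pixels
  if (is.array(tiles) && length(dim(tiles)) == 4) {
    return(matrix(tiles, ncol = dim(tiles)[4]) / rescale_divisor)
  }
  if (length(tiles) == 0) return(matrix(numeric(), nrow = 0, ncol = 0))
  vapply(tiles, function(a) as.numeric(a), numeric(length(tiles[[1]]))) / rescale_divisor
}
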