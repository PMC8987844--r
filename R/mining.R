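#' Harvest hard negatives: tiles a model wrongly calls positive
#'
#' The first-round classifier ("Model 1") typically flags sunlit leaves and
#' non-target yellow flowers. Scanning images that are known to contain no
#' target, every tile the model calls positive is a false positive by
#' construction; these tiles are harvested so they can be added to the
#' negative class before retraining ("Model 2").
#'
#' @param model a trained `tile_cnn` (or classifier function).
#' @param negative_images target-free image sources (tibble with
#'   `source_id` + `image`, named list of arrays or scenes, or paths).
#' @param chop a [chop_config()].
#' @param threshold optional probability cut-off override.
#' @return a `mining_report`: list with `n_images_scanned`,
#'   `n_tiles_scanned`, `n_harvested`, `per_source` (tibble of per-image
#'   counts) and `tiles` (a `tile_set` of the harvested tiles, all
#'   `label = 0`).
#' @export
harvest_false_positives <- function(model, negative_images, chop = chop_config(),
                                    threshold = NULL) {
  unwrap <- function(x) if (inherits(x, "scene")) x$image else x
  if (is.list(negative_images) && !is.data.frame(negative_images)) {
    negative_images <- purrr::map(negative_images, unwrap)
  }
  src <- as_source_tibble(negative_images, "negative_images")
  tiles <- purrr::map2(src$image, src$source_id, chop_image, config = chop) |>
    dplyr::bind_rows()
  if (nrow(tiles) > 0) {
    pred <- if (is.null(threshold)) predict_tiles(model, tiles) else predict_tiles(model, tiles, threshold = threshold)
    tiles$probability <- pred$probability
    tiles$call <- pred$call
  } else {
    tiles$probability <- numeric()
    tiles$call <- integer()
  }
  harvested <- tiles[tiles$call == 1L, , drop = FALSE]
  harvested$label <- rep(0L, nrow(harvested))
  harvested$size_class <- rep(NA_character_, nrow(harvested))
  harvested$split <- rep("train", nrow(harvested))
  class(harvested) <- c("tile_set", class(harvested))
  per_source <- tiles |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      n_tiles = dplyr::n(),
      n_false_positive = sum(.data$call == 1L),
      .groups = "drop"
    )
  structure(
    list(
      n_images_scanned = nrow(src),
      n_tiles_scanned = nrow(tiles),
      n_harvested = nrow(harvested),
      per_source = per_source,
      tiles = harvested
    ),
    class = "mining_report"
  )
}

#' @export
print.mining_report <- function(x, ...) {
  cat(sprintf(
    "<mining_report> %d images, %d tiles scanned, %d false-positive tiles harvested\n",
    x$n_images_scanned, x$n_tiles_scanned, x$n_harvested
  ))
  invisible(x)
}

#' Retrain with harvested hard negatives (Model 1 -> Model 2)
#'
#' Appends the harvested false-positive tiles to the *training* negatives of
#' the base dataset (never to validation, to avoid leakage) and trains a
#' fresh network of the same architecture. Tile identity is
#' `source_id` + grid position; a harvested tile that collides with a
#' validation tile is an error.
#'
#' @param base_dataset the `tile_set` used for the first-round model.
#' @param harvested a `mining_report` or its `tiles` component.
#' @param model_template a `tile_cnn` whose architecture/config to reuse, or
#'   `NULL` for defaults sized to the data.
#' @param config a [train_config()] override.
#' @param augment an [augment_config()] for training.
#' @param seed RNG seed for initialization and training.
#' @return list with `model` (the retrained `tile_cnn`) and `dataset` (the
#'   augmented `tile_set`).
#' @export
retrain_with_hard_negatives <- function(base_dataset, harvested,
                                        model_template = NULL, config = NULL,
                                        augment = augment_config(), seed = 1) {
  tiles <- if (inherits(harvested, "mining_report")) harvested$tiles else harvested
  if (nrow(tiles) > 0) {
    val <- base_dataset[base_dataset$split == "validation", ]
    key <- function(d) paste(d$source_id, d$grid_row, d$grid_col)
    leak <- intersect(key(tiles), key(val))
    if (length(leak) > 0) {
      abort(sprintf(
        "%d harvested tile(s) are also in the validation set (e.g. %s): leakage",
        length(leak), leak[1]
      ))
    }
    tiles$label <- 0L
    tiles$split <- "train"
    keep <- intersect(names(base_dataset), names(tiles))
    dataset <- dplyr::bind_rows(base_dataset[keep], tiles[keep])
  } else {
    dataset <- base_dataset
  }
  class(dataset) <- unique(c("tile_set", class(dataset)))

  tile_px <- dim(dataset$pixels[[1]])[1]
  model <- if (is.null(model_template)) {
    build_network(tile_px, config %||% train_config(), seed = seed)
  } else {
    build_network(
      model_template$tile_size, config %||% model_template$config,
      conv_filters = model_template$conv_filters,
      dense_units = model_template$dense_units, seed = seed
    )
  }
  model <- train_network(model, dataset, config = model$config,
                         augment = augment, seed = seed)
  list(model = model, dataset = dataset)
}
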