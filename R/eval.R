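#' Confusion counts from binary calls and ground truth
#'
#' @param call integer/logical vector of model calls (1 = target).
#' @param label equal-length vector of ground-truth labels.
#' @return a one-row tibble of class `confusion_counts` with columns `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(call, label) {
  if (length(call) != length(label)) {
    abort(sprintf("length mismatch: %d calls vs %d labels", length(call), length(label)))
  }
  if (length(call) == 0) abort("need at least one call/label pair")
  call <- as.integer(call); label <- as.integer(label)
  if (!all(call %in% 0:1) || !all(label %in% 0:1)) {
    abort("calls and labels must be binary (0/1)")
  }
  out <- tibble(
    tp = sum(call == 1L & label == 1L),
    fn = sum(call == 0L & label == 1L),
    fp = sum(call == 1L & label == 0L),
    tn = sum(call == 0L & label == 0L)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Tile-level classification metrics
#'
#' Computes, from confusion counts:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, and Cohen's kappa `(p_o - p_e)/(1 - p_e)` with
#' `p_o` = accuracy and
#' `p_e = ((TP+FN)(TP+FP) + (TN+FN)(TN+FP)) / n^2`.
#' A metric whose denominator is zero is reported as `NA` and named in the
#' `undefined` list-column rather than silently propagated; perfect
#' agreement with `p_e = 1` (all mass in one agreeing cell) yields kappa 1.
#'
#' @param counts a [confusion_counts()] row (or anything with columns/fields
#'   `tp`, `fn`, `fp`, `tn`).
#' @return a one-row tibble of class `metrics_report`: `tp`, `fn`, `fp`,
#'   `tn`, `n`, `accuracy`, `recall`, `precision`, `kappa`, `undefined`.
#' @examples
#' classification_metrics(confusion_counts(
#'   call = c(rep(1, 45), rep(0, 55)),
#'   label = c(rep(1, 40), rep(0, 5), rep(1, 10), rep(0, 45))
#' ))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  stopifnot(length(tp) == 1, tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  n <- tp + fn + fp + tn
  if (n == 0) abort("empty confusion table")
  undefined <- character()

  accuracy <- (tp + tn) / n
  if (tp + fn > 0) recall <- tp / (tp + fn) else { recall <- NA_real_; undefined <- c(undefined, "recall") }
  if (tp + fp > 0) precision <- tp / (tp + fp) else { precision <- NA_real_; undefined <- c(undefined, "precision") }

  p_o <- accuracy
  p_e <- ((tp + fn) * (tp + fp) + (tn + fn) * (tn + fp)) / n^2
  if (p_e < 1) {
    kappa <- (p_o - p_e) / (1 - p_e)
  } else if (p_o == 1) {
    kappa <- 1
  } else {
    kappa <- NA_real_
    undefined <- c(undefined, "kappa")
  }

  out <- tibble(
    tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp), tn = as.integer(tn),
    n = as.integer(n),
    accuracy = accuracy, recall = recall, precision = precision, kappa = kappa,
    undefined = list(undefined)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Build the pure-cover tile test set
#'
#' The evaluation protocol chops images that are (nearly) fully covered by
#' the target and images entirely free of it, then draws a seeded sample of
#' test tiles — by default 500 tiles, balanced 250 positive / 250 negative.
#' Test images must be disjoint from the training sources.
#'
#' @param pure_positive_images,pure_negative_images image sources (tibble
#'   with `source_id` + `image`, named list of arrays or [make_scene()]
#'   scenes, or file paths).
#' @param chop a [chop_config()].
#' @param n_tiles total test tiles to draw.
#' @param positive_fraction share of positive tiles (default 0.5).
#' @param seed sampling seed.
#' @return a `tile_set` tibble with `label` and `split = "test"`.
#' @export
build_test_set <- function(pure_positive_images, pure_negative_images,
                           chop = chop_config(), n_tiles = 500,
                           positive_fraction = 0.5, seed = NULL) {
  unwrap <- function(x) {
    if (inherits(x, "scene")) return(x$image)
    x
  }
  coerce <- function(src, arg) {
    if (is.list(src) && !is.data.frame(src)) src <- purrr::map(src, unwrap)
    as_source_tibble(src, arg)
  }
  pos <- coerce(pure_positive_images, "pure_positive_images")
  neg <- coerce(pure_negative_images, "pure_negative_images")
  maybe_seed(seed)

  chop_all <- function(src, label) {
    tiles <- purrr::map2(src$image, src$source_id, chop_image, config = chop) |>
      dplyr::bind_rows()
    tiles$label <- label
    tiles
  }
  pos_tiles <- chop_all(pos, 1L)
  neg_tiles <- chop_all(neg, 0L)

  n_pos <- round(n_tiles * positive_fraction)
  n_neg <- n_tiles - n_pos
  if (nrow(pos_tiles) < n_pos || nrow(neg_tiles) < n_neg) {
    abort(sprintf(
      "not enough tiles for a %d-tile test set: need %d positive (have %d) and %d negative (have %d)",
      n_tiles, n_pos, nrow(pos_tiles), n_neg, nrow(neg_tiles)
    ))
  }
  out <- dplyr::bind_rows(
    dplyr::slice_sample(pos_tiles, n = n_pos),
    dplyr::slice_sample(neg_tiles, n = n_neg)
  )
  out$split <- "test"
  out$size_class <- NA_character_
  class(out) <- c("tile_set", class(out))
  out
}

#' Evaluate a model on a labeled tile set
#'
#' @param model a trained `tile_cnn` (or classifier function).
#' @param test_set a `tile_set` with `label`.
#' @param threshold optional probability cut-off override.
#' @return a one-row `metrics_report` tibble.
#' @export
evaluate_model <- function(model, test_set, threshold = NULL) {
  pred <- predict_tiles(model, test_set, threshold = threshold)
  classification_metrics(confusion_counts(pred$call, test_set$label))
}

#' Cross-source transferability matrix
#'
#' Evaluates every model on every test set: cell `(m, t)` holds the metrics
#' of model `m`'s calls on test source `t`. High diagonal versus off-diagonal
#' kappa indicates that models transfer poorly across cameras.
#'
#' @param models named list of trained models.
#' @param test_sets named list of labeled `tile_set`s.
#' @param threshold optional probability cut-off override.
#' @return a tibble of class `transfer_matrix`: one row per model x test
#'   source with all counts and metrics.
#' @export
transfer_matrix <- function(models, test_sets, threshold = NULL) {
  if (length(models) < 1 || length(test_sets) < 1) {
    abort("need at least one model and one test set")
  }
  if (is.null(names(models))) names(models) <- sprintf("model_%d", seq_along(models))
  if (is.null(names(test_sets))) names(test_sets) <- sprintf("test_%d", seq_along(test_sets))
  out <- purrr::imap(models, function(m, mname) {
    purrr::imap(test_sets, function(ts, tname) {
      dplyr::mutate(
        evaluate_model(m, ts, threshold = threshold),
        model_source = mname, test_source = tname, .before = 1
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(out) <- c("transfer_matrix", class(out))
  out
}

#' Kappa table of a transferability matrix
#'
#' Wide layout: one row per model, one column per test source, plus an
#' `Average` row holding the arithmetic mean kappa per test source.
#'
#' @param tm a [transfer_matrix()] result.
#' @return a tibble.
#' @export
kappa_matrix <- function(tm) {
  wide <- tm |>
    dplyr::select("model_source", "test_source", "kappa") |>
    tidyr::pivot_wider(names_from = "test_source", values_from = "kappa")
  avg <- wide |>
    dplyr::summarise(dplyr::across(-"model_source", ~ mean(.x, na.rm = TRUE))) |>
    dplyr::mutate(model_source = "Average", .before = 1)
  dplyr::bind_rows(wide, avg)
}

#' @export
autoplot.transfer_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$test_source, .data$model_source,
                                       fill = .data$kappa)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$kappa))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = "test source", y = "model source", fill = "kappa") +
    ggplot2::theme_minimal()
}
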