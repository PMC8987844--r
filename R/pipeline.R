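#' Configuration for a full synthetic chopped-picture experiment
#'
#' Bundles every knob of the end-to-end protocol: scene synthesis for one
#' or more emulated cameras, dataset construction, first-round training
#' (Model 1), hard-negative mining and retraining (Model 2), the pure-cover
#' test protocol, the transferability matrix, and coverage overlays.
#'
#' @param cameras list of [camera_profile()]s; one model pair is trained per
#'   camera.
#' @param chop a [chop_config()].
#' @param train a [train_config()].
#' @param augment an [augment_config()].
#' @param conv_filters,dense_units network architecture (see
#'   [build_network()]).
#' @param scene_width_px,scene_height_px synthetic scene size.
#' @param n_train_scenes scenes per camera for training.
#' @param n_mining_scenes target-free distractor scenes per camera for
#'   false-positive harvesting.
#' @param n_test_pos,n_test_neg pure-cover / target-free scenes per camera
#'   for the test protocol.
#' @param length_range,cover_range sampling ranges for the corpus (see
#'   [make_corpus()]).
#' @param sunlit_leaf_fraction,nontarget_yellow_flower_count distractor
#'   levels used in the mining and test negatives.
#' @param n_per_class training tiles kept per label class.
#' @param n_test_tiles,positive_fraction test-set protocol (default 500
#'   tiles, balanced).
#' @param purity_threshold green-foliage purity cut-off for positives.
#' @param seed global experiment seed.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(cameras = list(
                              camera_profile("camA"),
                              camera_profile("camB", gain = c(0.55, 0.50, 0.90),
                                             offset = c(15, 20, 25))
                            ),
                            chop = chop_config(),
                            train = train_config(),
                            augment = augment_config(),
                            conv_filters = c(32, 64), dense_units = 64,
                            scene_width_px = 200, scene_height_px = 200,
                            n_train_scenes = 60, n_mining_scenes = 8,
                            n_test_pos = 4, n_test_neg = 4,
                            length_range = c(10, 160), cover_range = c(0.15, 0.6),
                            sunlit_leaf_fraction = 0.06,
                            nontarget_yellow_flower_count = 6,
                            n_per_class = 1000,
                            n_test_tiles = 500, positive_fraction = 0.5,
                            purity_threshold = 0.2,
                            seed = 1) {
  stopifnot(
    inherits(chop, "chop_config"), inherits(train, "train_config"),
    inherits(augment, "augment_config"),
    all(purrr::map_lgl(cameras, inherits, "camera_profile"))
  )
  structure(
    list(
      cameras = cameras, chop = chop, train = train, augment = augment,
      conv_filters = conv_filters, dense_units = dense_units,
      scene_width_px = scene_width_px, scene_height_px = scene_height_px,
      n_train_scenes = n_train_scenes, n_mining_scenes = n_mining_scenes,
      n_test_pos = n_test_pos, n_test_neg = n_test_neg,
      length_range = length_range, cover_range = cover_range,
      sunlit_leaf_fraction = sunlit_leaf_fraction,
      nontarget_yellow_flower_count = nontarget_yellow_flower_count,
      n_per_class = n_per_class,
      n_test_tiles = n_test_tiles, positive_fraction = positive_fraction,
      purity_threshold = purity_threshold,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

# next free versioned run directory under root
new_run_dir <- function(root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  i <- 1L
  repeat {
    d <- file.path(root, sprintf("run-%03d", i))
    if (!dir.exists(d)) {
      dir.create(d)
      return(d)
    }
    i <- i + 1L
  }
}

#' Run the full synthetic experiment
#'
#' For every camera profile: synthesizes a training corpus, builds the
#' labeled dataset, trains Model 1, harvests false positives from
#' target-free distractor scenes and retrains as Model 2, and builds a
#' pure-cover test set. Then computes the model x test-source
#' transferability matrices for both model generations, coverage estimates
#' with overlays on held-out scenes, and writes every artifact (manifests,
#' model checkpoints, history and metrics CSVs, kappa matrices, overlay
#' PNGs, a provenance log) into a fresh versioned run directory.
#'
#' @param config a [pipeline_config()].
#' @param out_dir root output directory; each invocation creates a new
#'   `run-NNN` inside (never overwriting an earlier run).
#' @param verbose print progress.
#' @return (invisibly) a list with `run_dir`, per-camera `models`
#'   (`model1`, `model2`), `datasets`, `mining` reports, `test_sets`,
#'   `transfer` (tibbles for both generations) and `coverage` (tibble of
#'   held-out coverage estimates vs truth).
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = tempfile("tilecover_runs"),
                           verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  run_dir <- new_run_dir(out_dir)
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  cam_seeds <- sample.int(2^31 - 2, length(config$cameras) * 4)
  outputs <- character()
  keep <- function(path) { outputs <<- c(outputs, path); path }

  base_spec <- function(cam, ...) {
    scene_spec(
      width_px = config$scene_width_px, height_px = config$scene_height_px,
      camera = cam, ...
    )
  }

  models1 <- list(); models2 <- list(); datasets <- list()
  mining <- list(); test_sets <- list(); holdout <- list()

  for (i in seq_along(config$cameras)) {
    cam <- config$cameras[[i]]
    sd0 <- cam_seeds[(i - 1) * 4 + 1]
    say("camera %s: synthesizing %d training scenes", cam$name, config$n_train_scenes)
    corpus <- make_corpus(
      config$n_train_scenes, base_spec(cam),
      length_range = config$length_range, cover_range = config$cover_range,
      seed = sd0
    )
    utils::write.csv(
      dplyr::select(corpus, -"scene"),
      keep(file.path(run_dir, sprintf("corpus_%s.csv", cam$name))),
      row.names = FALSE
    )
    dataset <- build_dataset_from_corpus(
      corpus, config$chop,
      purity_threshold = config$purity_threshold,
      n_per_class = config$n_per_class, seed = sd0 + 1
    )
    utils::write.csv(
      dplyr::select(dataset, -"pixels"),
      keep(file.path(run_dir, sprintf("dataset_%s.csv", cam$name))),
      row.names = FALSE
    )
    datasets[[cam$name]] <- dataset

    say("camera %s: training Model 1", cam$name)
    m1 <- build_network(config$chop$tile_size_px, config$train,
                        conv_filters = config$conv_filters,
                        dense_units = config$dense_units, seed = sd0 + 2)
    m1 <- train_network(m1, dataset, augment = config$augment, seed = sd0 + 2,
                        verbose = verbose)
    models1[[cam$name]] <- m1
    save_model(m1, keep(file.path(run_dir, sprintf("model1_%s", cam$name))))

    say("camera %s: mining false positives", cam$name)
    mining_scenes <- purrr::map(seq_len(config$n_mining_scenes), function(j) {
      make_scene(base_spec(
        cam, target_cover_fraction = 0,
        sunlit_leaf_fraction = config$sunlit_leaf_fraction,
        nontarget_yellow_flower_count = config$nontarget_yellow_flower_count,
        seed = sd0 + 100 + j
      ))
    })
    names(mining_scenes) <- sprintf("%s_mine%02d", cam$name, seq_along(mining_scenes))
    rep_i <- harvest_false_positives(m1, mining_scenes, config$chop)
    mining[[cam$name]] <- rep_i
    jsonlite::write_json(
      list(
        n_images_scanned = rep_i$n_images_scanned,
        n_tiles_scanned = rep_i$n_tiles_scanned,
        n_harvested = rep_i$n_harvested,
        per_source = rep_i$per_source
      ),
      keep(file.path(run_dir, sprintf("mining_%s.json", cam$name))),
      auto_unbox = TRUE, digits = NA
    )

    say("camera %s: retraining as Model 2 (%d hard negatives)", cam$name, rep_i$n_harvested)
    # same training seed as Model 1: the only difference between the two
    # generations is the harvested hard negatives
    m2 <- retrain_with_hard_negatives(
      dataset, rep_i, model_template = m1, augment = config$augment, seed = sd0 + 2
    )$model
    models2[[cam$name]] <- m2
    save_model(m2, keep(file.path(run_dir, sprintf("model2_%s", cam$name))))

    say("camera %s: building %d-tile test set", cam$name, config$n_test_tiles)
    pos_scenes <- purrr::map(seq_len(config$n_test_pos), function(j) {
      make_scene(base_spec(cam, target_cover_fraction = 1, seed = sd0 + 200 + j))
    })
    neg_scenes <- purrr::map(seq_len(config$n_test_neg), function(j) {
      make_scene(base_spec(
        cam, target_cover_fraction = 0,
        sunlit_leaf_fraction = config$sunlit_leaf_fraction / 2,
        nontarget_yellow_flower_count = max(1, config$nontarget_yellow_flower_count %/% 2),
        seed = sd0 + 300 + j
      ))
    })
    names(pos_scenes) <- sprintf("%s_testpos%02d", cam$name, seq_along(pos_scenes))
    names(neg_scenes) <- sprintf("%s_testneg%02d", cam$name, seq_along(neg_scenes))
    test_sets[[cam$name]] <- build_test_set(
      pos_scenes, neg_scenes, config$chop,
      n_tiles = config$n_test_tiles, positive_fraction = config$positive_fraction,
      seed = sd0 + 4
    )

    # cover-recovery holdout: contiguous stands (clusters well above tile
    # scale), the regime where tile-level cover tracks pixel cover
    holdout[[cam$name]] <- purrr::map(1:3, function(j) {
      make_scene(base_spec(
        cam, target_cover_fraction = 0.2 + 0.2 * j,
        inflorescence_length_px = 100,
        seed = sd0 + 400 + j
      ))
    })
  }

  say("computing transferability matrices")
  transfer1 <- transfer_matrix(models1, test_sets)
  transfer2 <- transfer_matrix(models2, test_sets)
  for (gen in 1:2) {
    tm <- if (gen == 1) transfer1 else transfer2
    utils::write.csv(
      dplyr::mutate(tm, undefined = purrr::map_chr(.data$undefined, paste, collapse = ";")),
      keep(file.path(run_dir, sprintf("metrics_model%d.csv", gen))),
      row.names = FALSE
    )
    utils::write.csv(
      kappa_matrix(tm),
      keep(file.path(run_dir, sprintf("kappa_model%d.csv", gen))),
      row.names = FALSE
    )
  }

  say("estimating coverage on held-out scenes")
  coverage <- purrr::imap(holdout, function(scenes, cam_name) {
    purrr::imap(scenes, function(sc, j) {
      map <- estimate_coverage(models2[[cam_name]], sc, config$chop)
      ov <- render_overlay(sc, map, alpha = 0.4)
      write_image(ov, keep(file.path(run_dir, sprintf("overlay_%s_%d.png", cam_name, j))))
      tibble(
        camera = cam_name, scene = j,
        truth_cover = sc$cover_fraction,
        estimated_cover = map$positive_fraction
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  utils::write.csv(coverage, keep(file.path(run_dir, "coverage.csv")), row.names = FALSE)

  prov <- list(
    package_version = as.character(utils::packageVersion("tilecover")),
    r_version = R.version.string,
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    config_hash = rlang::hash(config[setdiff(names(config), "seed")]),
    outputs = basename(outputs)
  )
  jsonlite::write_json(prov, file.path(run_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(files = c(basename(outputs), "provenance.json", "manifest.json")),
                       file.path(run_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    run_dir = run_dir,
    models = list(model1 = models1, model2 = models2),
    datasets = datasets, mining = mining, test_sets = test_sets,
    transfer = list(model1 = transfer1, model2 = transfer2),
    coverage = coverage
  ))
}
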