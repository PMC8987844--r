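#' Camera color profile for synthetic scenes
#'
#' Emulates shooting the same vegetation with different cameras: after a
#' scene is rendered, each channel is mapped `gain * value + offset` and
#' clipped to `[0, 255]`. Two profiles with different gains/offsets stand in
#' for two camera sources in transferability experiments.
#'
#' @param name profile identifier used as the source/camera id.
#' @param gain,offset length-3 numeric vectors (R, G, B).
#' @return a `camera_profile` object.
#' @export
camera_profile <- function(name = "default", gain = c(1, 1, 1), offset = c(0, 0, 0)) {
  stopifnot(length(gain) == 3, length(offset) == 3)
  structure(list(name = name, gain = gain, offset = offset), class = "camera_profile")
}

# scene palette: chosen to emulate late-summer fallow vegetation with
# flowering goldenrod and its classic confusers (sun-bleached foliage and
# other yellow flowers)
scene_palette <- function() {
  list(
    foliage = c(45, 110, 40), foliage_sd = c(10, 14, 10),
    soil = c(120, 90, 55), soil_sd = c(12, 10, 9),
    sky = c(165, 200, 235), sky_sd = c(5, 5, 5),
    target = c(200, 180, 30), target_sd = c(25, 25, 20),
    sunlit_leaf = c(190, 215, 125), sunlit_leaf_sd = c(12, 12, 14),
    nontarget_flower = c(235, 225, 95), nontarget_flower_sd = c(10, 10, 15)
  )
}

#' Specification of a synthetic vegetation scene
#'
#' Describes one generated field image: a green/brown vegetated background
#' (optionally with a sky band), dark-yellow target flower clusters whose
#' characteristic diameter is the inflorescence reference length (so it
#' drives the S/M/L size class), plus distractors — sunlit pale leaves and
#' non-target yellow flowers — that are *not* part of the ground-truth mask.
#'
#' @param width_px,height_px scene dimensions.
#' @param target_cover_fraction fraction of pixels to cover with target
#'   clusters, in `[0, 1]`. Values `>= 0.995` render a fully covered
#'   ("pure target") scene.
#' @param inflorescence_length_px characteristic cluster diameter in pixels
#'   (the size-class reference length, normally in `[10, 300]`).
#' @param n_soil_patches brown soil patches drawn under the vegetation.
#' @param sky_fraction fraction of image height filled with sky at the top.
#' @param sunlit_leaf_fraction fraction of pixels covered by pale sunlit
#'   foliage distractors.
#' @param nontarget_yellow_flower_count number of non-target yellow flower
#'   patches (a brighter, slightly greener yellow than the target; patch
#'   diameters 30–90 px, independent of the target's inflorescence length).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param camera a [camera_profile()] applied last.
#' @param seed RNG seed; `NULL` draws from the current RNG state.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(width_px = 200, height_px = 200,
                       target_cover_fraction = 0.3,
                       inflorescence_length_px = 40,
                       n_soil_patches = 4, sky_fraction = 0,
                       sunlit_leaf_fraction = 0, nontarget_yellow_flower_count = 0,
                       noise_sd = 8, camera = camera_profile(), seed = NULL) {
  stopifnot(
    is_count(width_px), is_count(height_px),
    target_cover_fraction >= 0, target_cover_fraction <= 1,
    inflorescence_length_px >= 1,
    sunlit_leaf_fraction >= 0, sunlit_leaf_fraction < 1,
    noise_sd >= 0, inherits(camera, "camera_profile")
  )
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      target_cover_fraction = target_cover_fraction,
      inflorescence_length_px = as.integer(round(inflorescence_length_px)),
      n_soil_patches = n_soil_patches, sky_fraction = sky_fraction,
      sunlit_leaf_fraction = sunlit_leaf_fraction,
      nontarget_yellow_flower_count = nontarget_yellow_flower_count,
      noise_sd = noise_sd, camera = camera, seed = seed
    ),
    class = "scene_spec"
  )
}

# linear indices (into an H x W matrix) of pixels inside a rotated ellipse
ellipse_idx <- function(H, W, cx, cy, a, b, th) {
  r <- max(a, b)
  x0 <- max(1, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  y0 <- max(1, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer())
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, length(ys), length(xs)) - cy
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  inside <- which((u / a)^2 + (v / b)^2 <= 1)
  yy <- ys[(inside - 1) %% length(ys) + 1]
  xx <- xs[(inside - 1) %/% length(ys) + 1]
  (xx - 1) * H + yy
}

paint <- function(img, idx, color, sd) {
  if (length(idx) == 0) return(img)
  HW <- dim(img)[1] * dim(img)[2]
  for (ch in 1:3) {
    img[idx + (ch - 1) * HW] <- clamp(color[ch] + rnorm(length(idx), 0, sd[ch]), 0, 255)
  }
  img
}

# Greedy cluster placement with a rejection/slide-in loop: full clusters are
# dropped at random while they fit the remaining budget; a cluster that
# would overshoot is slid in from a random edge (binary search on the
# visible area) so the realized cover lands within tolerance of the target.
place_targets <- function(H, W, f, L, max_iter = 800) {
  mask <- matrix(FALSE, H, W)
  A <- H * W
  if (f <= 0) return(mask)
  if (f >= 0.995) { mask[] <- TRUE; return(mask) }
  target_px <- round(f * A)
  it <- 0
  while (sum(mask) < target_px - max(1, round(0.01 * A)) && it < max_iter) {
    it <- it + 1
    need <- target_px - sum(mask)
    a <- L / 2 * runif(1, 0.80, 1.10)
    b <- L / 2 * runif(1, 0.55, 0.90)
    th <- runif(1, 0, pi)
    if (pi * a * b <= need + 0.03 * A) {
      mask[ellipse_idx(H, W, runif(1, 1, W), runif(1, 1, H), a, b, th)] <- TRUE
    } else {
      edge <- sample.int(4, 1)
      pos <- runif(1)
      r <- max(a, b)
      center_at <- function(t) {
        switch(edge,
          c(-r + t * (W / 2 + r), pos * H),
          c(W + r - t * (W / 2 + r), pos * H),
          c(pos * W, -r + t * (H / 2 + r)),
          c(pos * W, H + r - t * (H / 2 + r))
        )
      }
      lo <- 0; hi <- 1
      for (k in 1:18) {
        mid <- (lo + hi) / 2
        ct <- center_at(mid)
        n_new <- sum(!mask[ellipse_idx(H, W, ct[1], ct[2], a, b, th)])
        if (n_new < need) lo <- mid else hi <- mid
      }
      ct <- center_at(lo)
      mask[ellipse_idx(H, W, ct[1], ct[2], a, b, th)] <- TRUE
    }
  }
  realized <- sum(mask) / A
  if (f >= 0.05 && f <= 0.95 && abs(realized - f) > 0.05) {
    abort(sprintf(
      "could not realize target cover %.2f (got %.3f): clusters of diameter %d do not fit",
      f, realized, round(L)
    ))
  }
  mask
}

#' Render a synthetic vegetation scene with its ground-truth mask
#'
#' Deterministic under `spec$seed`: the same spec yields a bit-identical
#' image and mask. The truth mask marks target-flower pixels only;
#' distractors are deliberately excluded so they act as hard negatives.
#'
#' @param spec a [scene_spec()].
#' @return a `scene`: list with `image` (`H x W x 3`, intensities 0–255),
#'   `mask` (`H x W` logical), `cover_fraction` (realized mask fraction) and
#'   `spec`.
#' @examples
#' sc <- make_scene(scene_spec(seed = 7))
#' sc$cover_fraction
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  maybe_seed(spec$seed)
  H <- spec$height_px; W <- spec$width_px
  pal <- scene_palette()

  # foliage base with low-frequency blotches + fine texture
  coarse <- 8L
  img <- array(0, c(H, W, 3))
  blotch_rows <- rep(seq_len(coarse), each = ceiling(H / coarse))[seq_len(H)]
  blotch_cols <- rep(seq_len(coarse), each = ceiling(W / coarse))[seq_len(W)]
  for (ch in 1:3) {
    blotch <- matrix(rnorm(coarse * coarse, 0, 16), coarse, coarse)
    img[, , ch] <- pal$foliage[ch] + blotch[cbind(
      rep(blotch_rows, times = W), rep(blotch_cols, each = H)
    )] + rnorm(H * W, 0, pal$foliage_sd[ch])
  }

  for (i in seq_len(spec$n_soil_patches)) {
    idx <- ellipse_idx(H, W, runif(1, 1, W), runif(1, 1, H),
                       runif(1, 8, 28), runif(1, 6, 18), runif(1, 0, pi))
    img <- paint(img, idx, pal$soil, pal$soil_sd)
  }

  if (spec$sky_fraction > 0) {
    rows <- seq_len(max(1L, round(spec$sky_fraction * H)))
    idx <- as.vector(outer(rows, (0:(W - 1)) * H, "+"))
    img <- paint(img, idx, pal$sky, pal$sky_sd)
  }

  if (spec$sunlit_leaf_fraction > 0) {
    covered <- matrix(FALSE, H, W)
    goal <- spec$sunlit_leaf_fraction * H * W
    guard <- 0
    while (sum(covered) < goal && guard < 500) {
      guard <- guard + 1
      idx <- ellipse_idx(H, W, runif(1, 1, W), runif(1, 1, H),
                         runif(1, 4, 12), runif(1, 3, 8), runif(1, 0, pi))
      covered[idx] <- TRUE
      img <- paint(img, idx, pal$sunlit_leaf, pal$sunlit_leaf_sd)
    }
  }

  if (spec$nontarget_yellow_flower_count > 0) {
    # patches of a co-flowering non-target species; patch diameter is
    # independent of the target's inflorescence length and large enough
    # that whole tiles can fall inside a patch
    for (i in seq_len(spec$nontarget_yellow_flower_count)) {
      d <- runif(1, 30, 90)
      idx <- ellipse_idx(H, W, runif(1, 1, W), runif(1, 1, H),
                         d / 2 * runif(1, 0.8, 1.1), d / 2 * runif(1, 0.55, 0.9),
                         runif(1, 0, pi))
      img <- paint(img, idx, pal$nontarget_flower, pal$nontarget_flower_sd)
    }
  }

  mask <- place_targets(H, W, spec$target_cover_fraction, spec$inflorescence_length_px)
  img <- paint(img, which(mask), pal$target, pal$target_sd)

  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)

  cam <- spec$camera
  for (ch in 1:3) {
    img[, , ch] <- cam$gain[ch] * img[, , ch] + cam$offset[ch]
  }
  img <- round(clamp(img, 0, 255))

  structure(
    list(image = img, mask = mask, cover_fraction = mean(mask), spec = spec),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %d x %d px, target cover %.3f (camera %s)\n",
    x$spec$width_px, x$spec$height_px, x$cover_fraction, x$spec$camera$name
  ))
  invisible(x)
}

#' Ground-truth labeled tiles of a synthetic scene
#'
#' Chops the scene and derives per-tile truth from the mask: a tile is
#' positive when at least `truth_threshold` of its pixels are target
#' (default 0.5 — the "mostly covered by flowers" convention for positive
#' tiles).
#'
#' @param scene a [make_scene()] result.
#' @param chop a [chop_config()].
#' @param truth_threshold masked-fraction cut-off for a positive tile.
#' @param source_id tile source identifier; defaults to the camera name.
#' @return a `tile_set` tibble with `mask_fraction`, `label`, `size_class`
#'   columns; grid attached as in [chop_image()].
#' @export
scene_tiles <- function(scene, chop = chop_config(), truth_threshold = 0.5,
                        source_id = NULL) {
  stopifnot(inherits(scene, "scene"))
  sid <- source_id %||% scene$spec$camera$name
  tiles <- chop_image(scene$image, chop, source_id = sid)
  grid <- chop_grid(tiles)
  t <- grid$tile_size_px; s <- grid$stride_px
  tiles$mask_fraction <- purrr::map2_dbl(tiles$grid_row, tiles$grid_col, function(r, co) {
    mean(scene$mask[r * s + seq_len(t), co * s + seq_len(t)])
  })
  tiles$label <- as.integer(tiles$mask_fraction >= truth_threshold)
  len <- scene$spec$inflorescence_length_px
  tiles$size_class <- ifelse(
    tiles$label == 1L,
    if (len >= 10 && len <= 300) classify_size(len) else "OUT_OF_RANGE",
    NA_character_
  )
  attr(tiles, "grid") <- grid
  class(tiles) <- c("tile_set", class(tiles))
  tiles
}

#' Generate a reproducible corpus of synthetic scenes
#'
#' Per-scene inflorescence lengths and cover fractions are sampled from the
#' given ranges; everything is driven by `seed`, and the returned manifest
#' records every sampled spec. A length range spanning `[10, 300]` yields
#' scenes in all three size classes.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param base a [scene_spec()] providing the shared settings.
#' @param length_range integer range the inflorescence reference length is
#'   drawn from (uniformly).
#' @param cover_range range the target cover fraction is drawn from.
#' @param seed corpus seed.
#' @return a tibble (the corpus manifest) with one row per scene:
#'   `scene_id`, `camera`, `inflorescence_length_px`, `size_class`,
#'   `target_cover_fraction`, `cover_fraction` (realized), `seed`, and a
#'   `scene` list column.
#' @export
make_corpus <- function(n_scenes, base = scene_spec(), length_range = c(10, 300),
                        cover_range = c(0.15, 0.6), seed = 1) {
  if (!is_count(n_scenes)) abort("`n_scenes` must be a whole number >= 1")
  stopifnot(inherits(base, "scene_spec"))
  maybe_seed(seed)
  lengths <- sample(length_range[1]:length_range[2], n_scenes, replace = TRUE)
  covers <- runif(n_scenes, cover_range[1], cover_range[2])
  seeds <- sample.int(.Machine$integer.max - 1, n_scenes)
  scenes <- purrr::pmap(list(lengths, covers, seeds), function(len, cov, sd) {
    sp <- base
    sp$inflorescence_length_px <- as.integer(len)
    sp$target_cover_fraction <- cov
    sp$seed <- sd
    make_scene(sp)
  })
  tibble(
    scene_id = sprintf("%s_scene%03d", base$camera$name, seq_len(n_scenes)),
    camera = base$camera$name,
    inflorescence_length_px = as.integer(lengths),
    size_class = classify_size(lengths),
    target_cover_fraction = covers,
    cover_fraction = purrr::map_dbl(scenes, "cover_fraction"),
    seed = seeds,
    scene = scenes
  )
}

#' Labeled tiles for every scene of a corpus
#'
#' Convenience wrapper: [scene_tiles()] per corpus row, bound into a single
#' `tile_set` whose `source_id` is the scene id.
#'
#' @param corpus a [make_corpus()] manifest.
#' @inheritParams scene_tiles
#' @return a `tile_set` tibble.
#' @export
corpus_tiles <- function(corpus, chop = chop_config(), truth_threshold = 0.5) {
  out <- purrr::map2(corpus$scene, corpus$scene_id, function(sc, id) {
    scene_tiles(sc, chop, truth_threshold, source_id = id)
  }) |> dplyr::bind_rows()
  class(out) <- c("tile_set", class(out))
  out
}
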