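# Internal helpers shared across modules.

# An isolated, resumable RNG stream: `rng(expr)` evaluates expr with the
# stream's own .Random.seed swapped into the global environment, then saves
# the advanced state back.  Lets augmentation streams stay reproducible
# without clobbering the caller's RNG.
new_rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  outer <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(outer)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", outer, envir = globalenv())
  }
  function(expr) {
    outer <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", envir = globalenv())
      if (is.null(outer)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", outer, envir = globalenv())
      }
    })
    force(expr)
  }
}

# set.seed only when a seed is given
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && abs(x - round(x)) < 1e-8
}

# validate an H x W x 3 numeric array with values in [0, 255]
check_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort(sprintf("`%s` must be an H x W x 3 numeric array", arg))
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    abort(sprintf("`%s` must hold intensities in [0, 255]", arg))
  }
  invisible(image)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
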