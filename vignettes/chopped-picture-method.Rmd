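---
title: "The chopped-picture method for mapping flowering invasive cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chopped-picture method for mapping flowering invasive cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Dense stands of flowering tall goldenrod (*Solidago altissima*) form
amorphous yellow patches in late-summer imagery. Object detectors assume
compact objects; semantic segmentation needs pixel-accurate ground truth
that is impractical for thousands of mm-scale florets. The chopped-picture
method treats cover mapping as *tile classification*: chop the image into
small overlapping squares, decide per tile whether the target is present,
and read cover off the mosaic of calls. The classifier never needs to know
where in the tile the flowers are, so curating training data reduces to
sorting small crops into two piles.

`tilecover` implements that pipeline end to end: tiling geometry, dataset
curation rules, a compact seeded CNN training engine, false-positive
mining, tile-level evaluation with Cohen's kappa, cross-camera
transferability, and coverage overlays — plus a synthetic scene generator
that stands in for field imagery in all tests.

## Tiling geometry

Tiles are squares of `tile_size_px` (default 30) whose origins advance by
`stride = tile_size_px * (1 - overlap_fraction)`; the default 50% overlap
gives stride 15, so interior pixels are seen by four tiles. Conventions this implementation fixes:

* tile indices are 0-based and row-major; tile `(r, c)` has top-left pixel
  `(c*stride, r*stride)`; rectangles are half-open;
* remainder pixels at the right/bottom edge that cannot form a full tile
  are dropped — the classifier needs fixed-size input and partial tiles
  have no defined semantics;
* the stride must come out integral (30 px tiles with overlap 0.5 or 0 do;
  25 px tiles with overlap 0.5 are rejected rather than silently rounded).

## Dataset rules

Positive tiles must be *mostly flower*. In field practice that judgement
is made by eye; tilecover operationalizes the under-20%-green-leaves rule with an explicit pixel
predicate — HSV hue in [70°, 170°], saturation ≥ 0.25, value ≥ 0.15 — and
drops positive tiles whose green fraction reaches `purity_threshold = 0.2`.
The three cut-offs are arguments, because any fixed color rule is a proxy
for a human judgement; the defaults classify mid-greens and shaded foliage
as "green" while leaving dark-yellow flowers, soil and sky out.

Size stratification uses the pixel length of the primary inflorescence
branch: S = 10–50, M = 51–100, L = 101–300 px. When several size classes
are available, per-class quotas keep each represented in the sampled
training set (`mix_sizes = TRUE`).

The train/validation split defaults to 80/20, stratified by label and
seeded; validation tiles are never augmented.

Augmentation applies width/height shifts, horizontal flip and zoom, with
intensities rescaled by 1/255; magnitudes default to mild conventional
settings (shift 0.1, zoom 0.2), all configurable. Edge gaps
left by a transform are filled by nearest-pixel replication; augmentation
streams own an isolated RNG so a seed fully determines the emitted
sequence regardless of other RNG use.

## The classifier and its training engine

The training regime is fixed: epochs 30, batch 128, dropout 0.2, Adam at
0.001, binary cross-entropy, ReLU, zero padding, a single sigmoid output.
The network is deliberately shallow — the inputs are 30 px crops — and the
default architecture is

```
conv 3x3x32 (same, ReLU) -> maxpool 2x2 ->
conv 3x3x64 (same, ReLU) -> maxpool 2x2 ->
flatten -> dense 64 (ReLU) -> dropout 0.2 -> dense 1 (sigmoid)
```

with `conv_filters` and `dense_units` as knobs. No R deep-learning
framework is assumed: the package carries its own small convolution engine
(im2col/GEMM forward and backward in RcppArmadillo) with mini-batch Adam
in R. Correctness is enforced by finite-difference gradient checks in the
test suite (relative error < 1e-5 on every parameter group) and by a
color-threshold oracle on a linearly separable toy task. All stochastic
elements — Glorot initialization, batch composition, augmentation draws,
dropout masks — derive from R's RNG, so a seed reproduces training
bit-for-bit on the same machine. The decision threshold on the sigmoid
output is 0.5 and configurable; training accuracy uses the same threshold.

Numerical details: binary cross-entropy clamps probabilities to
`[1e-12, 1 - 1e-12]`; dropout is inverted (mask then scale by
`1/(1-rate)`) so prediction needs no rescaling; max-pooling drops an odd
trailing row/column (30 → 15 → 7).

## Hard-negative mining

Model 1 is trained on ordinary positives and negatives. Scanning images
known to be target-free, every tile called positive is a false positive by
construction; these are harvested (tile-level, not object-level — tiles
are the pipeline's atomic unit) and appended to the *training* negatives
only, never to validation, and a harvested tile colliding with a
validation tile by identity (source, grid position) is an error. Model 2
is then trained from scratch **at the same seed as Model 1**, so the
harvested negatives are the only difference between the generations; with
independent seeds, initialization noise alone can swamp the mining effect.
One mining round is the default.

## Evaluation

Confusion counts come from pure-cover test images (nearly 100% target) and
target-free images, chopped at 50% overlap, with a seeded sample of 500
tiles. The positive/negative composition defaults
to balanced 250/250 with `positive_fraction` as a knob. Metrics are
accuracy `(TP+TN)/n`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)`; kappa uses `p_o` = accuracy and
`p_e = ((TP+FN)(TP+FP) + (TN+FN)(TN+FP))/n²`. Degenerate denominators are
reported as `NA` plus an entry in an `undefined` column — never silently 0
— and `p_e = 1` with perfect agreement yields kappa 1. The transferability
matrix evaluates every model on every test source; the `Average` row of
`kappa_matrix()` is the arithmetic column mean.

## Coverage fusion

Under 50% overlap each stride cell is covered by up to four tiles. Cell
probability is the *mean* over covering tiles, thresholded at 0.5; mean
fusion is deterministic and uses every prediction; coloring whole tiles
was the alternative considered and rejected.
Cells right/below the last full footprint stay untinted and outside the
cover estimate.

## The synthetic scene generator

Scenes emulate the survey regime: a green foliage base with low-frequency
blotches and brown soil patches (optional sky band); dark-yellow target
clusters — textured ellipses whose characteristic diameter is the
inflorescence reference length, placed greedily with a slide-in edge
search so realized cover lands within ±0.05 of the target for fractions in
[0.1, 0.9]; distractors *outside* the truth mask (pale sunlit foliage, and
brighter yellow patches of a co-flowering non-target species, 30–90 px
across — large enough that whole tiles can fall inside them, which is what
makes them genuine hard negatives); Gaussian pixel noise; and a per-camera
channel gain/offset applied last, before a single quantization. Tile truth
is `mask fraction ≥ 0.5` ("mostly covered"), configurable.

The default second camera profile, gain (0.55, 0.50, 0.90) and offset
(15, 20, 25), emulates an underexposed/overcast capture: the target stays
recognizably warm but much duller. This reproduces the qualitative
cross-camera regime — a model trained on the bright profile misses the
dull target almost entirely, while each model stays strong on its own
profile — the expected failure mode for colour-keyed classifiers under a
different exposure or overcast light.

What the generator does **not** emulate: perspective and scale variation
within a scene, specular highlights, motion blur, compression artifacts,
and the texture continuity of real canopies. Tests passing on synthetic
scenes therefore demonstrate the pipeline's mechanics and its documented
failure modes, not field-ready accuracy.

## Problem sizes and study conditions in the tests

The test suite and the acceptance script run the protocol at desk scale,
chosen as the package's own standard conditions: training corpora of 60
scenes of 200×200 px (≈ 8,600 tiles, 2,500 sampled, 2,000 in the training
split) for the default network at 10 epochs; 24-scene corpora with a
reduced network (8/16 filters, dense 32, 6 epochs, batch 64) for the
replicated mining and transferability experiments; 500-tile balanced test
sets; three replicate seeds for the mining comparison.

## Known limitations

* **Tile/cluster scale.** Tile-level cover systematically mis-estimates
  pixel cover when target clusters are about the tile size: even a
  *perfect* tile classifier (truth labels at threshold 0.5) overestimates
  blobby masks by up to ~0.15–0.19 at mid cover with 40 px clusters and
  30 px tiles, and no single tile threshold fixes it (a scan over
  thresholds 0.4–0.8 leaves a worst-case error of ~0.11). Boundary cells
  dominate. Coverage recovery is therefore evaluated — and should be
  trusted — on contiguous stands with cluster diameter ≳ 3× the tile side
  (we use 100 px), the regime the method is designed for; there Model 1
  recovers cover within ±0.05 and Model 2 within ±0.08 per scene.
* **Color-driven classification.** On synthetic scenes the discriminative
  signal is color/texture statistics; real cross-site generalization
  involves structure the generator does not model.
* **Purity predicate vs camera cast.** The green-foliage rule operates on
  rendered colors; a strong color cast can move flower pixels across the
  hue boundary. Camera profiles here are chosen so that "green" remains
  green, as a human curator would judge per camera.
* **Single mining round.** Iterating mining is supported in principle but
  untested beyond one round.
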