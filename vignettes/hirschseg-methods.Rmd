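---
title: "Methods: patch-based segmentation and zone calling for Hirschsprung histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based segmentation and zone calling for Hirschsprung histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The diagnostic problem

Hirschsprung disease is a congenital aganglionosis of the distal bowel:
enteric ganglion cells are absent from a distal segment, and the affected
bowel typically shows hypertrophic cholinergic nerve trunks. Surgical
planning depends on locating three regions along the resected specimen —
the normally ganglionated (ganglionic) zone, the aganglionic zone, and the
transition zone between them, which contains both scattered ganglion cells
and hypertrophic nerves. On haematoxylin–eosin (H&E) sections this is a
subtle pattern-recognition task with meaningful interobserver variability.

`hirschseg` implements a two-model consensus workflow for this task:

1. **Model 1** segments *ganglion cells* and *normal nerves* against
   background (3 classes) in 256×256 px patches of ×10 H&E slide scans.
2. **Model 2** segments *hypertrophic nerves* against background
   (2 classes) in the same patches.
3. A per-patch **decision table** combines the two into a zone call:

   | model 1 positive | model 2 positive | call         |
   |------------------|------------------|--------------|
   | yes              | no               | ganglionic   |
   | yes              | yes              | transition   |
   | no               | yes              | aganglionic  |
   | no               | no               | no tissue    |

   Transition patches carry a review flag: they are exactly the patches a
   pathologist must scrutinise, because both element types coexist there.

Clinical slide archives cannot ship with an R package, so the package
includes a synthetic-histology generator that emulates the geometry and
stain appearance of the three zones with per-pixel ground truth. Every
stage — tiling, dataset assembly, training, prediction, zone calling — is
exercised and tested end to end on generated cohorts.

## The synthetic slide generator

`scene_spec()` + `render_slide()` draw a 2048×1280 px canvas (the ×10 scan
geometry; any multiple of the 256 px patch size is allowed) containing:

* **Background**: an eosin-pink base colour with a stationary Gaussian
  noise texture. The texture is generated as a 320×320 noise block tiled
  modulo across the canvas — statistically indistinguishable from
  per-pixel noise at the network's receptive-field scale while keeping
  large-cohort rendering fast.
* **Normal nerves**: near-vertical wavy ribbons 3–6 px wide, drawn in
  ganglionic and transition patch columns.
* **Hypertrophic nerves**: the same geometry at 10–20 px width, drawn in
  aganglionic and transition columns. The width ranges are disjoint by
  construction (the spec of the scene validates this), so "hypertrophic"
  is a measurable property: a distance-transform width estimate separates
  the two ribbon populations in every rendered slide.
* **Ganglion cells**: non-overlapping filled ellipses with 8–16 px
  semi-axes and a darker nucleus, placed only inside a configurable
  *submucosal band* (default: the middle 70% of the canvas height),
  reflecting the histological constraint that ganglion cells occur in the
  submucosal/myenteric layers — a cell-like object outside those layers
  is not a ganglion cell.
* Optionally, **brown-like artifacts**: soft brown blobs blended into a
  chosen fraction of patches (`apply_artifact()`), emulating the
  overlapping-tissue colouration that can be mistaken for ganglion cells.
  Artifacts alter the image only; ground truth masks never change.

Element colours live in `he_colour_config()`, not in code. Every labelled
pixel is guaranteed to differ from the median background colour by more
than the configured contrast threshold (0.08 in RGB distance), which the
test suite asserts; this is what makes the desk-scale learning problem
well-posed.

Zone truth is defined per patch column: a slide's `zone_layout` assigns
one zone per 256 px column, and `zone_truth` replicates it over patch
rows. Element placement respects the layout (no ganglion cells in
aganglionic columns, no hypertrophic nerves in ganglionic columns), which
is exactly the consistency the decision table later exploits. Nerve
ribbons span the full canvas height in distinct "lanes" of their column
so that every patch of a tissue column contains tissue — a deliberate
simplification that makes per-patch zone truth exact.

Morphology densities default to 2 ganglion cells per patch row and 4
nerves per compatible column. Neither density nor size is calibrated to
real tissue — published sources for this workflow do not quantify them —
so they are package defaults chosen to make the classes separable at the
network's scale, fixed once here and used by all tests.

**Determinism.** A `scene_spec` carries its seed; `render_slide()` is
byte-reproducible given the spec. Cohort seeds derive per-slide seeds via
a fixed integer mix (`hash(cohort_seed, index)` kept below 2^31), so
`render_cohort()` is reproducible as a whole, and `render_cohort()`
accepts a `transform` callback so very large cohorts can be processed
streaming rather than materialised (490 full-geometry slides would not
fit in memory).

## What the generator does *not* emulate

Real H&E histology has crypts, muscle layers, lymphoid tissue, stain
gradients, folds, out-of-focus regions, immature ganglion cells, and
artifact diversity far beyond one brown blob. Passing the desk-scale
tests therefore demonstrates that the *pipeline* is correct (tiling,
masks, training loop, consensus logic) and that the models can learn
colour/width-separable structures; it does not demonstrate clinical
performance. Published accuracies from patient cohorts (on the order of
92%) are not reproducible from this package and are not claimed; the test
suite instead asserts the scaled-down analogues (≥ 0.90 validation pixel
accuracy and ≥ 0.90 zone recovery on synthetic cohorts).

## Dataset pipeline

The curation pipeline mirrors the study design it re-implements:

1. `expand_cohort(slides, factor = 5)` — each slide plus 4 augmented
   variants (108 slides → 540). Slide-level augmentation uses the
   shape-preserving ops (horizontal/vertical flips, 180° rotation, colour
   normalisation); 90°/270° rotations are available for square patches
   but would change the canvas shape at slide level. All rotations are
   multiples of 90° so masks are permuted, never interpolated — arbitrary
   angles would corrupt class labels along edges.
2. `patchify()` — exact non-overlapping tiling; 2048×1280 → 40 patches of
   256×256. `unpatchify()` is its exact inverse, driven by each patch's
   `(row, col)` origin rather than list order, and errors on missing or
   duplicated positions.
3. `filter_targetless()` — patches without at least one pixel of the
   model's target classes are set aside (this is where the bulk of a
   cohort is excluded: most tissue is background for any one model).
4. `inject_background()` — a configurable fraction (default 0.10; the
   source protocol does not state one) of targetless patches is added
   back so the network sees negative context. The appended count is the
   largest `k` with `k/(n+k) ≤ fraction`.
5. `split_80_20()` — seeded shuffle, `floor(0.8 n)` to training. The
   shuffle uses R's Mersenne–Twister under a fixed seed, which is
   platform-stable; this replaces an explicit hash-based tie-break with
   the same reproducibility guarantee. The split is at patch level for
   fidelity to the source protocol; note that patch-level splitting lets
   near-duplicate tissue from one slide appear on both sides of the
   split, so validation accuracy should be read as in-distribution
   performance, not slide-level generalisation.

`colour_norm` matches each channel's mean and (population) standard
deviation to a reference (`he_reference_moments()` by default); no
clipping is applied inside the op so the moment match is exact, and
values are snapped back to 8-bit levels when written to disk.

## The segmentation models

Both models are small U-Nets built by `build_unet()` from a
`unet_config()`:

* encoder: `depth` levels (default 3) of two 3×3 same-padding
  convolutions + ReLU, 2×2 max-pooling between levels, `base_filters`
  (default 16) channels at the top, doubled per level;
* decoder: nearest-neighbour 2× upsampling, a 1×1 "up-projection"
  convolution that halves the channels before skip concatenation (the
  classic up-convolution; it also halves the decoder's arithmetic), then
  two 3×3 convolution + ReLU blocks;
* head: 1×1 convolution to per-class scores, softmax over classes.

Training (`train_segmenter()`) is mini-batch Adam (default batch 8,
learning rate 1e-3) on the pixel-wise multinomial cross-entropy.
Because background dominates the pixel budget, the loss supports class
weighting; `class_weights = "balanced"` uses inverse-frequency weights
estimated from the training split, clipped to `[0.25, 10]` and normalised
to mean 1. Inputs are standardised with fixed constants
(`(x − 0.8)/0.15`). He initialisation and the shuffle order are seeded,
so a run is reproducible on one device; determinism across BLAS
implementations is not claimed.

The numerical kernels (im2col + GEMM convolution, pooling, upsampling,
loss) are compiled single-precision code; a layer-by-layer
double-precision reference implementation is retained in R and the test
suite verifies (a) fused vs. reference agreement to float precision and
(b) backpropagated gradients against central finite differences, exactly
at the head and to within ReLU-kink noise below it.

The per-epoch history records training accuracy (accumulated from the
forward passes) and validation pixel accuracy (`TrainingHistory`);
`detect_plateau()` finds the earliest epoch from which every
`window`-length stretch of the curve has range below a tolerance. The
protocol-scale default of 120 epochs is kept in `training_config()`;
desk-scale runs in the tests and the acceptance script use 24 slides and
3 epochs, which this problem's colour/width separability makes
sufficient (validation pixel accuracy plateaus above 0.99).

**Accuracy** is pixel-wise: correct predictions over all predictions.
The underlying formula is ambiguous between pixel- and patch-level
readings; pixel-wise is implemented because the models emit per-pixel
masks, and `cmd_evaluate()` additionally reports a patch-level accuracy
(fraction of patches ≥ 99% correct) for transparency.

## Zone calling

`detect_presence()` turns a predicted patch mask into a flag: present iff
the mask holds at least `min_positive_pixels` target pixels. The
threshold defaults to 64 px (≈ 0.1% of a patch): a ≥1-pixel rule would
let single-pixel noise flip zone calls, and presence is provably monotone
non-increasing in the threshold (tested). Model 1's two positive classes
are pooled by default — either ganglion cells or normal nerves make a
patch "model-1 positive", matching the expected-segmentation description
of the ganglionic zone. A stricter `ganglion_only` mode is provided
because the transition zone is described by ganglion cells specifically;
which reading the original workflow intended is ambiguous, so both are
implemented and the default is the permissive one.

`call_slide()` applies the rule per patch and the decision table to the
flags. `(absent, absent)` is deliberately labelled `no_tissue` rather
than aganglionic: background-only patches produce no segmentation under
either model, and conflating "no tissue" with "aganglionic tissue" would
overstate the call. `zone_accuracy()` scores calls against a truth grid,
optionally excluding `no_tissue` calls.

## Problem sizes used by tests and the acceptance script

* Desk-scale training: 24 uniform-zone slides of 1024×512 px (8 patches
  each; ≈ 190 patches, ≈ 110 training items per model after curation),
  depth-3 / 16-filter U-Nets, 3 epochs, balanced class weights — chosen
  as the smallest cohort that exercises every pipeline stage while both
  models exceed 0.99 validation pixel accuracy.
* Zone recovery: 30 held-out uniform slides of the same geometry.
* Accounting checks run at full geometry (2048×1280, 40 patches/slide;
  490 slides streamed through the `transform` callback) and the
  expansion check at 512×256 so 540 slides fit comfortably in memory.

## Known limitations

* Synthetic morphology is a stand-in; no claim of clinical validity.
* Patch-level 80/20 splitting leaks near-duplicate tissue between splits
  (noted above); a slide-level split option is the obvious extension.
* The loss, optimiser, batch size and input normalisation of the original
  workflow are unpublished; the defaults here are the package's own and
  are documented, not claimed as faithful.
* Exact reproducibility holds per device/BLAS; histories may differ in
  the last float digits across platforms.
* The decision table operates per patch; no spatial smoothing or
  neighbourhood context is applied to zone calls, and transition-zone
  length measurement is out of scope.
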