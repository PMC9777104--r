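---
title: "stainseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stainseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the pieces of `stainseg` fit together, which
parameters matter, and where the design was genuinely open — the choices we
made and why.

## The problem and the approach

Hematoxylin stains nuclei purple-blue; eosin stains cytoplasm and stroma
pink. The exact colors vary by laboratory, scanner and fixation, which is
the main obstacle to transferring a nucleus segmenter between cohorts.
Rather than normalizing colors to a template, the package learns features
that are invariant to that variation: an encoder is pretrained with a
contrastive objective on pairs of differently-augmented (including
color-jittered) views of the same patch, so agreeing across photometric
perturbations is the training signal itself. The pretrained encoder then
anchors a supervised segmentation network.

## Encoder

Five stages, each halving the spatial side; for a 256×256 input the sides
are 128/64/32/16/8 and the S4 bottleneck map is 8×8. The arithmetic only
holds when the input side is divisible by 32, which the configuration
enforces. Stage composition:

* **S0** — two 3×3 convolutions (the first stride 2), batch-norm + GELU,
  closed by a WHDC block.
* **S1, S2** — MBConv stages: 1×1 expansion (×4) → 3×3 depthwise
  convolution (first block stride 2) → squeeze-excitation (hidden width
  `Cin/4`) → 1×1 projection, with a residual when shapes match. S1 is
  closed by a second WHDC block with the same hyperparameters but its own
  learned weights (the minimal reading of "same parameter setting"); S2 has
  none.
* **S3, S4** — transformer stages: stride-2 max-pool entry with a 1×1
  channel projection, then pre-norm blocks of multi-head self-attention
  with a learned 2D relative-position bias table (indexed by row/column
  offset) and an FFN with expansion 4. Batch-norm lives in the
  convolutional stages, layer-norm in the transformer stages.

Stage widths and depths are not dictated by the architecture itself, so two
presets are provided: `full` at the CoAtNet-0 scale (channels
64/96/192/384/768, depths 2/2/3/5/2, 8 heads) and `tiny`
(16/24/32/64/128, depth 1, 2 heads) sized for CPU training and the test
suite. All package tests and the acceptance script use `tiny`; `full`
is exercised only for parameter-count and projection-head checks, since
training it is a GPU-scale undertaking.

One published constant deserves a note: the contrastive recipe uses
224×224 inputs, but 224 is not divisible by 32 at the fifth halving
(224 → 7, not 8). The bottleneck-side statement of 8×8 is only consistent
with a 256 input, so `input_size` is exposed in the configuration and the
package defaults to 256.

## WHDC

The weighted hybrid dilated convolution block is the architectural core.
Four 3×3 convolutions with dilation rates 3, 6, 9, 18 run in cascade
(branch *k* consumes branch *k−1*'s output), each followed by batch-norm
and GELU; padding equals the rate, so shape is preserved even when the
effective kernel span (37 pixels at rate 18) exceeds the map. Three open
points and our resolutions:

* **What the sigmoid gates read.** The source of the four gate weights is
  unstated beyond "derived dynamically". We compute each gate from its own
  branch: `w_k = sigmoid(a' gap(branch_k) + b)`, a learned scalar read-out
  of the branch's globally pooled features — the smallest mechanism that is
  both "self-weighting" and dynamic. Gates are scalars, not per-channel
  vectors ("four weights").
* **Channel bookkeeping.** Concatenating the four gated branches with the
  input gives 5C channels; nothing says how C is restored. We append a 1×1
  projection after the channel attention, because the block must be
  shape-preserving to close stages S0/S1.
* **Attention bottleneck rounding.** The channel-attention hidden width is
  `max(1, round(5C/r))` with r = 16, so small test widths stay valid.

## Contrastive objective

The projection head is two weight matrices with a ReLU between and no
biases (the head's equations are more precise than the prose "single-layer
MLP", and we follow the equations); the hidden width equals the encoder
output width, the output is 128-dimensional. The bottleneck fed to the head
is the global average pool of the S4 map — the encoder must emit a vector,
and pooling is the standard way to get one. NT-Xent uses cosine similarity
with temperature 0.07; the denominator for anchor *i* runs over all other
2N−1 projections. Pretraining uses SGD, lr 0.001, momentum 0.9 (momentum is
unstated; 0.9 is the universal default), batch 2, 50 epochs. Batch 2 gives
only two negatives per anchor, so a note is emitted for batches below 8.
The head is discarded after pretraining, per contrastive convention; only
the encoder initializes the segmentation network.

## Decoder and losses

Five 4×4 stride-2 transposed convolutions double the resolution from 8 to
256. The skip wiring is the only one consistent with five layers, the
stated sizes and four attention gates: decoder layer *k* ∈ 1..4 upsamples,
then concatenates the attention-gated skip from stage `s_{4−k}` (gated by
the pre-upsampling decoder state); layer 5 has no skip — no full-resolution
encoder map exists — and no batch-norm or ReLU, ending in a sigmoid.
Decoder widths mirror the encoder stage widths. The attention gate is the
additive form: 1×1 maps on skip and (nearest-upsampled) gating signal, sum,
ReLU, 1×1, sigmoid, multiply into the skip.

Losses: `BCE` is the pixel mean with predictions clamped to
`[1e-7, 1-1e-7]`; `Dice` loss uses smoothing `1e-6` so two empty masks
score a perfect 0; the combined loss is `0.4·BCE + 0.6·Dice`. Reductions
are means over pixels, Dice per image then averaged over the batch.
Thresholding uses `>=` (the boundary rule is unstated; one must be chosen
and documented). Adam runs with β₁ = 0.5, β₂ = 0.999, lr 2e-4. The encoder
is fine-tuned by default (`freeze_encoder` exposes the ablation arm), and
training applies aligned geometric augmentation (flips, 90° rotations) to
image/mask pairs.

## Patch pipeline

Whole-slide images are resized to 1024 (bilinear for images,
nearest-neighbor for masks — nearest is the only choice that cannot invent
labels), cut into four non-overlapping 512 tiles in row-major order, and
200 random 256 crops are drawn per tile with offsets uniform over the valid
positions, from a stream owned by the pipeline. 23 sources therefore yield
23 × 4 × 200 = 18,400 crops. The crop set is kept as a coordinate index
over the resized sources rather than 18,400 duplicated pixel files: every
crop is a deterministic view, retrievable with `read_crop()`, and
`materialize = TRUE` writes the files when a consumer needs them on disk.
Coordinates are 0-based, row-major, with half-open crop windows.

## Synthetic data: what it does and does not emulate

The generator paints filled ellipses (random center, semi-major axis from
`radius_range`, eccentricity from `eccentricity_range`, orientation uniform
on [0, π)) in hematoxylin-like purple (base RGB 0.35/0.22/0.55, jittered
per nucleus) over an eosin-like pink background (0.92/0.78/0.86, jittered
per image) with a smooth low-frequency texture. Stain domains emulate
inter-laboratory variation: separate hue shifts for the purple and pink
pixel classes (the hematoxylin hue band is [220°, 300°]; the synthetic
nucleus hue is ≈264°, the background ≈326°), brightness/contrast scaling,
and additive Gaussian noise. Images are quantized to the 8-bit grid so a
PNG round trip is bit-exact, and everything is a pure function of
`(spec, domain, seed)`.

What it deliberately does not model: chromatin texture, true
Beer–Lambert stain mixing, and realistic touching-nuclei boundaries. A
model that passes the synthetic tests has demonstrated that the
architecture, losses, optimization and bookkeeping work end to end — it has
*not* demonstrated clinical-grade accuracy on real H&E tissue, which
requires the real multi-organ corpora and GPU-scale training.

Default scene parameters (64-pixel patches, 4–6 nuclei of radius 5–12 px,
eccentricity below 0.6) were chosen once to give nucleus densities and
size/shape variation visually comparable to 40× H&E crops at small scale;
the non-overlap option uses rejection sampling capped at 100 attempts per
nucleus so runtime is bounded.

## Metrics

AJI follows the canonical aggregated-Jaccard procedure: ground-truth
instances in ascending label order each claim the *unused* predicted
component with maximal pairwise Jaccard (ties to the smaller predicted
label, for determinism); matched intersections/unions accumulate into
numerator/denominator; unmatched ground truth contributes its size, and all
unclaimed predicted components are added to the denominator. The printed
formula in the source text has garbled indices, so the reference
implementation it cites is what we follow. Binary network outputs are
instanced by 8-connected component labeling before AJI (nuclei are
blob-like; 4-connectivity is available). Dataset summaries report the mean
and *sample* standard deviation (n−1), matching the ± convention of the
benchmark tables.

Degenerate conventions: Dice of two empty masks is 1; precision on an
empty prediction and recall on an empty ground truth are reported as 1 with
a warning; AJI of two empty instance maps is 1.

## Numerical and engineering choices

* Reverse-mode autodiff on a define-by-run tape; convolutions via
  im2col/col2im (C++) and BLAS matrix multiplication; depthwise and pooling
  kernels in C++. Every primitive and composite block is validated against
  central finite differences in the test suite.
* Batch-norm uses the statistics of the current map during training
  (momentum 0.1, ε = 1e-5 running estimates for inference), since the
  training loops process one image at a time inside a batch-accumulated
  loss.
* He-style initialization throughout; relative-bias tables start near zero
  (sd 0.02).
* All randomness flows through seeded `rng_stream` objects that snapshot
  R's RNG state, so package code never perturbs the caller's RNG; one run
  seed fans out into named sub-streams (data, augmentation, init, order).
* Checkpoints are single RDS files with a format tag, version, config
  header and parameter tree; batch-norm state environments are frozen to
  tagged lists on save.
* Instance masks travel as 16-bit unsigned TIFF (labels to 65535, exact
  round trip); images as 8-bit PNG.

## Problem sizes used by the tests and acceptance script

The suite exercises the published patch-extraction scale exactly
(23 synthetic 1000×1000 sources → 18,400 indexed crops) and runs the
two-stage training at CPU scale: `tiny` preset, 64×64 patches, 8 training
and 4 held-out images, 2 pretraining epochs and 40 fine-tuning epochs —
sizes chosen so the whole suite completes in minutes while still training
the full architecture end to end. The end-to-end run asserts held-out pixel
Dice above 0.8.

## Known limitations

* Touching nuclei merge into single components in the binary output, so
  AJI on crowded scenes is much lower than pixel Dice; instance-level
  post-processing (e.g. watershed) is out of scope.
* The contrastive stage with batch 2 is faithful to the recipe but is a
  weak learning signal; it mainly serves as initialization.
* The autodiff engine is sized for the `tiny` preset; the `full` preset
  constructs and runs, but training it on CPU is impractical.
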