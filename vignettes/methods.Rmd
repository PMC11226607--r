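---
title: "Region-pooled graph convolution for leaf image classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-pooled graph convolution for leaf image classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its tests do and do not
demonstrate.

## The model

Visual symptoms of nutrient deficiency and disease on leaves are local:
chlorotic margins, necrotic spots, lesions. A backbone CNN followed by
global average pooling (GAP) summarizes the whole image in one C-vector and
can wash those regions out. The architecture implemented here keeps a
regional decomposition and models interactions between regions explicitly:

1. **Backbone feature map.** A convolutional backbone maps the preprocessed
   224×224×3 image to its final spatial activation map, h×w×C. Adapters are
   provided for Xception, ResNet-50, Inception-V3 and MobileNet-V2 (encoded
   layer by layer after the reference implementations, with exact parameter
   accounting) and for a deliberately small three-block "tiny" backbone
   (64×64 → 4×4×32, 6,032 parameters) that exists so the full pipeline
   trains in seconds on one CPU.
2. **Upsample + region grid.** The map is bilinearly upsampled to H×W
   (default 16×16) and cut into a g×g grid (default 4×4, ω = 16 regions) of
   non-overlapping tiles, each spatially averaged to one C-vector.
   Upsampling before tiling gives the tiles meaningful support when h and w
   are as small as 4–7.
3. **Spatial pyramid over regions.** The g×g grid of region descriptors is
   adaptively pooled at two bin resolutions i×i and j×j (default 2 and 3)
   and concatenated row-major, level i first, into P = i² + j² node vectors
   (default P = 13). Pooling the *grid of region descriptors* — rather than
   pooling inside each region — is what makes the pyramid encode
   inter-region structure; this is the intended reading of the stage, and
   the one this package commits to.
4. **Graph convolution.** Nodes form a complete graph: with Ã = A + I and
   D̃ its degree matrix, the propagation operator is
   Â = D̃^(−1/2) Ã D̃^(−1/2), which for the complete graph is exactly J/P.
   Two layers of G ← ReLU(Â G W + b) follow, channel width kept uniform
   (2048 for the large backbones; 1024 available as the narrow variant).
   The renormalized operator is used directly; the intermediate
   I + D^(−1/2) A D^(−1/2) form that motivates it is never materialized.
5. **Head.** GAP over the node axis, layer normalization, dropout 0.3, and
   a dense softmax over the Y classes. Training is SGD with momentum on
   categorical cross-entropy; the learning rate is divided by 5 after a
   fixed epoch; there is no early stopping. The best-validation model is
   checkpointed when a validation set exists, else the final model is used.

Because Â = J/P and GAP averages over nodes, the post-GAP feature is
invariant to any permutation of the node order, and identical node inputs
propagate to identical node outputs — both are tested properties, and
useful wiring checks.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `upsampleSize` (H) | 16 px | divisible by `grid`; larger H refines tile support |
| `grid` (g) | 4 | ω = g² = 16 regions |
| `levels` (i, j) | (2, 3) | P = i²+j² = 13 nodes; both ≤ g |
| `poolMode` | average | max selectable; see below |
| `gcnLayers` | 2 | 1 available as ablation |
| `gcnFeatures` | backbone C | 1024 as the narrow variant |
| `dropoutRate` | 0.3 | in the head only, not between GCN layers |
| `headNorm` | layer | batch selectable |
| learning rate | 10⁻³ | 0.007 shipped as the `alternate` preset |
| batch size | 12 | 8 in the `alternate` preset |
| epochs / drop | 150, ÷5 after 100 | step schedule, no early stopping |
| augmentation | rotation 20°, scale 0.20, translation 0.20, flip, noise | ±25°/±0.25 and Gaussian blur as alternates |

Where the protocol admits two published values (10⁻³ vs 0.007 learning
rate; batch 12 vs 8; rotation 20 vs 25; layer vs batch normalization in the
head; additive noise vs blur), the default is one of them and the other is
an explicit config alternate, so either recipe is reproducible from the
config file alone; both are recorded in run manifests. The exact (ω, i, j)
of full-scale experiments is a swept quantity, not a single published
constant, so all three are first-class config axes here.

**Average vs max pyramid pooling.** The pyramid-pooling literature commonly
uses max; this package defaults to average. Average makes the whole
upsample→regions→pyramid stage a single sparse linear operator (its
backward pass is a transpose, and constants propagate exactly — which the
tests exploit), while max is retained as an option with argmax-routed
gradients.

**Stratification.** Hold-out splits and folds are stratified per class.
With class-imbalanced collections at moderate n, an unstratified random
split makes test composition a large variance term; stratification is the
stabler default, and the split seed is stored in the plan file so any split
is exactly replayable.

**Macro averaging.** Aggregate precision/recall/F1 are unweighted means of
per-class values; zero-denominator cases (a class never predicted, or
absent) are defined as 0. Percentages in protocol tables are reported to
two decimals.

## The synthetic generator

`generateDataset()` renders each class as an elliptical "leaf" with a
class-specific base hue, carrying a class-specific count and colour of
circular lesion blobs, over a textured soil-coloured background with
additive Gaussian pixel noise (default sd 8/255). Pose, size, hue and
lesion placement jitter within a class; identical spec + seed is
bit-identical. Classes are therefore separable by simple colour statistics
— by construction a mean-colour linear probe reaches well above 90% — so a
correctly assembled network must be able to overfit a small sample quickly.
That is the point: the generator turns "does the architecture learn at
all?" into a sharp, deterministic test.

What it does *not* emulate: photorealistic leaves, real deficiency
symptomatology, occlusion, clutter, lighting variation, scale diversity, or
class boundaries that require texture rather than colour. Passing the
synthetic suite demonstrates correct mechanics, not field accuracy.

## Numerical choices

- **Bilinear convention.** Upsampling (and Grad-CAM resizing) uses
  half-pixel-centre sampling without corner alignment; target = source is
  the exact identity. The affine augmentation sampler is inverse-mapped
  with border replication, so zero magnitudes are the exact identity.
- **Adaptive bins.** Bin b of n over size S spans [⌊bS/n⌋, ⌈(b+1)S/n⌉) —
  bins overlap by at most one cell when n ∤ S; the oracle tests enumerate
  these boundaries explicitly.
- **Region grid.** The upsampled size must be divisible by g; there is no
  implicit padding.
- **Initialization.** Glorot-uniform weights, zero biases, all under
  derived seeds; batch-norm statistics start at (0, 1). Evaluation-mode
  forward passes are bit-deterministic.
- **Ties.** Top-k ranking breaks probability ties toward the lower class
  index (documented, tested).
- **Degenerate inputs.** Non-finite node features, shape mismatches,
  out-of-range labels, empty class folders, unreadable images, crops larger
  than the image, pyramid levels exceeding the grid: all are explicit
  errors, not silent coercions. A constant Grad-CAM map is defined as
  all-zeros rather than 0/0.
- **Loss floor.** Cross-entropy clips predicted probabilities at 1e-12.
- **Training divergence** (non-finite loss) aborts with a diagnostic rather
  than continuing.

## Parameter accounting

The four standard backbones are encoded layer by layer (convolutions,
separable and depthwise convolutions, batch-norm with and without scale
terms, the exact shortcut and branch structure), and `countParameters()`
sums every trainable weight plus tracked normalization statistics. The
totals reproduce the reference implementations exactly — 22,910,480
(Xception), 25,636,712 (ResNet-50), 23,851,784 (Inception-V3), 3,538,984
(MobileNet-V2) with 1000-class heads — so the published one-decimal
"millions" figures follow. Counts are invariant to input size, and removing
the classification head removes exactly its parameter count.

Pretrained weights are not bundled: requesting `pretrained = TRUE` is an
explicit error (never a silent random initialization). Random-initialized
feature extraction is available for shape-contract checks, and
frozen-backbone training (graph module + head only) is supported for the
large architectures; end-to-end gradient training is exercised on the tiny
backbone, whose backward pass is verified against finite differences of
the loss.

## Problem sizes used by the tests

The suite runs entirely on generated data: fixtures of 2–8 classes at
64×64, 40–400 images; the overfit check trains the tiny network on 60
images (3 classes) for up to 30 epochs at learning rate 0.02 over three
seeds; protocol tests use 2–5 folds with 2–3 epochs. These sizes were
chosen so the whole suite exercises every stage — including full training
loops — in a few minutes on one CPU; the acceptance script uses the same
scales.

## Known limitations

- No GPU path and no vectorized batching across images in the backbone:
  throughput is adequate for fixtures and small studies, not for field-scale
  datasets.
- Full-scale published-accuracy reproduction requires the public datasets
  and pretrained weights, neither of which ships with the package.
- The embedding export uses exact O(n²) t-SNE, suitable up to a few
  thousand points.
- The complete graph is fixed, not learned; alternative topologies exist
  only for testing propagation on non-uniform degrees.
- The assembled model's total parameter count for large backbones reflects
  exactly the declared layers (backbone + two C×C graph layers + head);
  no additional unreported dense layers are assumed.
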