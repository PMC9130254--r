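---
title: "Segmenting embryonic cartilage in micro-CT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting embryonic cartilage in micro-CT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Contrast-stained micro-CT resolves the soft tissues of an embryo at
micrometre resolution, but the cartilaginous structures of interest — the
nasal capsule being the extreme case — are thin, curved, structurally
inhomogeneous shells whose intensity separation from the surrounding
stained tissue is far too weak for thresholding or other classical
automatic segmentation. Expert manual annotation of one scan takes on the
order of a working day. `chondroseg` implements a fully automatic
slice-by-slice segmentation pipeline for this setting, together with the
quantitative follow-up (inscribed-sphere wall thickness) and a synthetic
phantom generator so that every stage can be exercised and validated
without access to a scan database.

## The network

The segmentation model is a U-shaped residual encoder-decoder operating on
whole axial slices. Working at full slice resolution matters: the volumes
exceed a thousand voxels per axis, a fully 3-D network at this size is not
tractable in memory, and patch-based training would discard the global
context needed to localize the cartilage, so the design keeps whole
cross-sections and processes the volume slice by slice.

* **Canvas.** Native volumes are bilinearly rescaled in-plane to a unified
  6 µm voxel size, then centre-cropped or zero-padded onto a fixed
  1792 × 1280 canvas, and standardized to zero mean, unit variance per
  volume. The canvas is divisible by $2^6$, so six exact halvings take a
  slice to 28 × 20 at the bottleneck.
* **Depth.** Six downsampling levels (two more than the classic four) so
  the receptive field covers the whole head at the bottleneck.
* **Residual blocks.** Three kinds. Downsampling blocks reduce resolution
  with strided 3 × 3 convolutions in the convolutional path and
  max-pooling + 1 × 1 convolution in the identity path; flat blocks keep
  the grid; upsampling blocks double it with 2 × 2 transposed convolutions
  against nearest-neighbour interpolation + 1 × 1 convolution in the
  identity path. Encoder features are concatenated into the decoder at the
  matching level, as in any U-Net. Within each block the convolutional
  path holds two convolutions with the activation between them, and the
  activation is applied again after the residual addition (the ResNet
  convention); the literature source for the architecture does not pin
  down block internals at this granularity, so this convention — and 3 × 3
  kernels, and "same" padding with the odd pixel on the high side — is a
  documented choice of this package.
* **Activations.** SELU with LeCun-normal initialization; no batch or
  layer normalization anywhere, self-normalization being the design's
  substitute. The ReLU ablation pairs with He-normal initialization.
* **Deep supervision.** Each decoder level carries an auxiliary
  1 × 1-convolution + sigmoid head whose output is nearest-neighbour
  upsampled to ground-truth resolution. With depth 6 that gives 7
  supervised outputs whose Dice losses are combined with weights, deepest
  to shallowest, 0.03, 0.05, 0.08, 0.12, 0.15, 0.2, 0.37 (the
  full-resolution head, weight 0.37, is the inference output).
* **Width.** Channel counts double per level from `base_filters` (default
  16). The source material never states channel counts; 16 keeps the
  depth-6 network buildable and trainable on desk hardware and the value
  is configurable.

All four architecture switches (residual blocks, deep supervision, SELU,
increased depth) plus augmentation-off are exposed as ablation variants via
`ablation_spec()`.

## Training

Dice loss (smoothing constant $10^{-6}$, computed per sample and averaged
over the mini-batch so large-cartilage slices do not dominate), Adam with
AMSgrad at learning rate $10^{-4}$, batch size 4, 50 epochs are the
defaults. Weights are taken from the epoch with the lowest validation loss.
The validation criterion uses the same deep-supervision composite as
training. Every stochastic source — initialization, shuffling, augmentation
— derives from one master seed.

Augmentation applies **two consecutive transforms** per training slice,
drawn jointly from a 6 × 6 probability matrix over ordered pairs of
\{rotation, vertical flip, gamma, elastic, scaling, no transform\} (the
36 entries sum to 1; e.g. elastic followed by elastic has probability
0.09). Rotation draws uniformly from ±10°, gamma from 0.9–1.1, scaling
from 0.9–1.1. Parameters are drawn independently per transform. Geometric
transforms use bilinear interpolation for the image, nearest-neighbour for
the mask, zero fill outside the canvas; gamma operates on a min-max
normalized copy (it is undefined on z-scored negative values) and restores
the original range. Elastic deformation displaces a coarse control grid
(spacing 128 px, displacement SD 10 px at full scale) and smoothly
upsamples the field bilinearly — the published description gives no elastic
parameters, so these are package choices sized to deform on the scale of
cartilage wall undulations without tearing thin structures; bilinear
rather than higher-order field upsampling keeps the field monotone and
shares one warp kernel with every other geometric operation.

The engine itself — convolution forward/backward via im2col and GEMM,
transposed convolution, pooling, the SELU/sigmoid calculus, Adam/AMSgrad —
is implemented in this package (RcppArmadillo kernels orchestrated from R),
since the R ecosystem available here provides no deep-learning runtime.
The backward pass is verified against finite differences in the unit
tests.

## Cross-validation and the subsampling rule

`make_folds()` builds seeded k-fold plans (the study design is sevenfold
over 14 samples: train on 12, validate on 2, every sample validated exactly
once). The ablation-style slice subsampling rule keeps every 30th slice
inside the contiguous axial range that contains cartilage and every 200th
slice outside it; "region containing cartilage" is read as that contiguous
index interval, which matches the anatomy (embryonic cartilage spans one
contiguous axial region).

## Sparse annotation

The annotation protocol this pipeline emulates labels only every third
axial slice by hand and fills the rest by interpolation.
`interpolate_sparse_labels()` implements the voxelwise reading: a linear
blend between the bracketing annotated slices, thresholded at 0.5 to
restore binarity. Voxelwise blending is deterministic and matches the
protocol's wording literally; shape-based interpolation would be an
alternative reading but introduces modelling choices the protocol does not
state.

## Wall thickness

Local thickness of a binary volume is defined per voxel as the diameter of
the largest sphere fully inscribed in the foreground that contains that
voxel's center. The implementation is the exact Euclidean distance
transform followed by descending-radius sphere stamping
(Hildebrand–Rüegsegger). One geometric convention matters: voxels are unit
cubes, so with $dt(c)$ the center-to-center distance from $c$ to the
nearest background voxel, the diameter assigned to a covered voxel is
$2\,dt - 1$ voxels; this makes a 5-voxel slab measure exactly 5 voxels
(30 µm at 6 µm) where the raw center-distance convention would give 6.
Volume boundaries count as background. The unit tests hold this
implementation to *exact* equality with a brute-force
sphere-enumeration oracle on random volumes. Thickness requires isotropic
voxels and a nonempty mask; anything else is an error. Histograms use
half-open bins (default width one voxel, 6 µm) and distributions are
compared by Spearman rank correlation of bin counts.

## The phantom generator

`generate_phantom()` renders the structural situation the method assumes,
not mouse anatomy: a bright soft-tissue "head" (a smooth ellipsoid,
emulating heavy-metal-stained tissue), a thin curved cartilage-like shell
(a deformed concentric ellipsoid surface, rasterized via an exact distance
transform so the wall thickness is a controlled parameter), an optional
planar septum whose upper fraction can be removed (`mutant_severity`,
emulating moderate-to-severe mutant morphology), Gaussian partial-volume
blur, and additive noise. Defaults: 6 µm voxels, 30 µm walls, contrast 4
background-noise SDs, noise SD 1500 on a 16-bit-like intensity scale
(tissue ≈ 20000, air ≈ 12000), blur 0.7 voxels. Air outside the head is
about as dark as the cartilage itself, so a global threshold cannot isolate
the shell — the premise that motivates a learned model — while the
ground-truth mask is fixed by the geometry before any intensity is drawn,
so staining quality, blur and noise never touch it. `staining_quality`
scales the cartilage contrast toward zero to emulate an improperly stained
sample. `generate_dataset()` mirrors a 14-scan study composition (10
controls, 3 mutants, 1 poorly stained) with per-sample wall thickness drawn
from 24–36 µm.

What the phantoms do **not** emulate: real anatomy (no turbinates, no
varying wall topology), reconstruction artifacts (beam hardening, rings),
scanner-dependent noise spectra, or staining gradients. Tests passing on
phantoms therefore demonstrate that the pipeline's machinery is correct and
that the model class can learn thin-shell segmentation from context; they
do not certify accuracy on real scans.

## Problem sizes used in the tests

The test suite runs everything at desk scale as the package's own choice of
test geometry: phantoms of 48 × 64 × 64 voxels, a depth-4, 8-filter network
on a 64 × 64 canvas, ten training phantoms with slice subsampling (strides
4/24), ten epochs at learning rate $10^{-3}$ (a deliberately faster rate
than the full-scale default, appropriate to the small network and short
schedule), batch 4, with the augmentation policy active (elastic control
spacing scaled to 32 px for 64-px slices). Under these conditions the
held-out volume Dice is expected above 0.8, while a `staining_quality ≈ 0`
phantom fails dramatically — the same failure mode the improperly stained
real sample shows. The full-scale network is built and its geometry
verified, but never trained in the tests.

## Numerical notes and known limitations

* **"Same" padding** follows the ceil-division convention with the extra
  pixel on the high side, which is what makes 1792 × 1280 reach exactly
  28 × 20 after six halvings.
* **Degenerate inputs** fail loudly: constant volumes cannot be
  standardized, gamma is refused on degenerate-range images, empty masks
  cannot be thickness-analysed, anisotropic voxels are rejected where
  isotropy is assumed.
* **Dice-loss saturation.** With a pure Dice objective and no
  normalization layers, pixels that become confidently wrong early can
  saturate the sigmoid (the gradient scales with $p(1-p)$) and freeze;
  Adam's scale-invariant updates then push logits to arbitrary magnitude.
  In multi-sample training with augmentation this is not observed, but
  when a deep configuration is forced to memorize a *single* slice it can
  lock into a coarse attractor (e.g. filling a hollow cross-section). The
  memorization sanity test therefore uses a shallow single-level
  configuration, which does not exhibit the attractor. This is a property
  of the objective worth knowing when adapting the pipeline.
* **SELU self-normalization** holds for the plain convolutional stack
  (pre-activation statistics stay near zero mean, unit-order SD at depth);
  residual additions accumulate variance by construction, so the
  normalization smoke test runs the non-residual configuration.
* **Mask resampling** is nearest-neighbour everywhere (bilinear would
  break binarity); the round-trip canvas → native is interpolation-limited
  rather than exact, and is held to Dice ≥ 0.99 on smooth phantom masks.
* **Bit-exact reproducibility** is promised per platform/BLAS build, not
  across them: convolution reductions go through GEMM, whose summation
  order differs between BLAS implementations.
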