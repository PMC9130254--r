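# chondroseg

Fully automatic segmentation of thin cartilaginous structures — the
embryonic nasal capsule being the motivating case — in large contrast-stained
micro-CT volumes, with quantitative wall-thickness follow-up. Designed for
developmental biologists and imaging scientists who today segment such
structures by hand, slice by slice, at a cost of a working day per scan.

Soft-tissue contrast in stained micro-CT is too weak for thresholding: the
cartilage is a thin curved shell whose intensity overlaps both the
surrounding tissue and other dark structures, so the segmentation has to
come from shape and context. `chondroseg` provides:

* **A deep residual encoder-decoder network** operating on whole axial
  slices (default canvas 1792 × 1280 px at a unified 6 µm voxel size).
  Six downsampling levels take a slice to 28 × 20 at the bottleneck;
  residual blocks (strided convolution vs. max-pool + 1 × 1 identity
  paths), SELU activations with LeCun-normal initialization in place of
  normalization layers, and deep supervision — an auxiliary sigmoid head
  per decoder level, with Dice-loss weights 0.03, 0.05, 0.08, 0.12, 0.15,
  0.2, 0.37 from deepest to shallowest. Every modification is an ablation
  switch. The training engine (im2col/GEMM convolutions, Adam/AMSgrad) is
  implemented in the package with RcppArmadillo kernels.
* **Dice objective**: DSC = 2·TP / (2·TP + FP + FN) for evaluation, its
  smoothed differentiable form for training, and the weighted
  deep-supervision composite.
* **A stochastic augmentation policy**: two consecutive transforms per
  training slice drawn jointly from a 6 × 6 probability matrix over
  ordered pairs of {rotation ±10°, vertical flip, gamma 0.9–1.1, elastic,
  scaling 0.9–1.1, none}.
* **k-fold cross-validation** (the study design: sevenfold over 14
  samples, train on 12, validate on 2) with per-sample volume Dice.
* **Local wall thickness** by the largest-inscribed-sphere definition,
  computed exactly via Euclidean distance transform + sphere stamping,
  with histograms and Spearman comparison of distributions.
* **A synthetic phantom generator** producing micro-CT-like volumes
  (bright tissue, dark air, thin low-contrast shell, optional
  septum-removal "mutants", controllable staining quality) with exact
  ground truth, so the whole pipeline trains and validates at desk scale
  with no external data.
* **Volume I/O**: NIfTI-1 (spacing in the header) and TIFF stacks
  (spacing in a JSON sidecar), bit-exact for integer data.

## Worked example

Generate a small phantom dataset, train the desk-scale network, segment a
held-out phantom and measure its wall thickness:

```r
library(chondroseg)

ds <- generate_dataset(6, base = phantom_preset("desk"),
                       n_mutant = 1, n_poor_staining = 0, seed = 42)
attr(ds, "composition")
#> control        mutant poor-staining
#>       5             1             0

canvas <- canvas_spec(64, 64, target_voxel = 6)
exs <- unlist(lapply(names(ds)[1:5], function(id)
  prepare_training_slices(ds[[id]]$volume, ds[[id]]$truth, canvas,
                          subsample_rule(24, 4))), recursive = FALSE)

net <- build_network(network_spec(64, 64, depth = 4, base_filters = 8),
                     seed = 1)
fit <- train_model(net, exs,
                   training_config(learning_rate = 1e-3, epochs = 10,
                                   batch_size = 4, seed = 1),
                   policy = augmentation_policy(
                     elastic_params = list(spacing = 32, max_disp = 4)))

seg <- segment_volume(ds[[6]]$volume, fit$network, canvas)
dice_coefficient(seg$mask, ds[[6]]$truth)
#> [1] 0.9001456

ds[[6]]$spec_used$shell_thickness
#> [1] 25.40985
tm <- local_thickness(ds[[6]]$truth)
tm
#> <cs_thickness_map> 9116 foreground voxels @ 6 um; thickness median 20.8 um, range [18.0, 23.4]
```

The Dice coefficient is the voxel overlap between the predicted and true
masks (1 = perfect); the held-out phantom — a severe "mutant" with most of
its septum removed — segments at 0.90 after ten desk-scale epochs. The
thickness median recovers the 25.4 µm wall this phantom was generated with
to within one 6 µm voxel (thin walls rasterize to odd voxel counts, here
3–4 voxels). At the published scale the same calls apply
with `network_spec()` and `canvas_spec()` defaults (1792 × 1280, depth 6),
whose structure report you can inspect without training:

```r
summarize_network(build_network(network_spec(), seed = 1))
#>   level height width channels
#> 1     0   1792  1280       16
#> ...
#> 7     6     28    20     1024
```

A command-line wrapper with `phantom`, `prep`, `train`, `cv`, `segment`,
`evaluate`, `thickness` and `ablate` subcommands is installed at
`inst/cli/chondroseg`.

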