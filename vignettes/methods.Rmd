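---
title: "Methods: pruning, pooling and rebalancing in dermcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pruning, pooling and rebalancing in dermcnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermcnn)
```

`dermcnn` implements a parameter-efficiency pipeline for convolutional
dermoscopy-image classifiers: an Xception-style separable-convolution
backbone is pruned by activation sparsity and retrained, the training set is
rebalanced with SMOTE and augmentation, and max pooling is replaced by the
Avg-TopK operator.  Everything runs at desk scale on synthetic data; this
vignette documents the model, the assumptions, and the numerical choices.

## Model representation

A network is an explicit directed acyclic graph of `layer_node()` objects
(`model_graph()`).  Supported kinds: `input`, `conv2d`,
`separable_conv2d`, `batch_norm`, `relu_activation`, `max_pool`,
`avg_topk_pool`, `add_merge`, `global_avg_pool`, `dense`, `softmax`.
Shapes are inferred per node (`infer_shapes()`), parameters counted exactly
(`parameter_count()`), and graphs round-trip through JSON
(`graph_to_json()` / `graph_from_json()`).  Tensors are column-major R
arrays laid out `(height, width, channel, sample)`; the compute-heavy
kernels (convolutions, pooling, batch-norm statistics) are implemented in
C++ via Rcpp.

`build_xception()` assembles the backbone: a two-convolution stem, an entry
flow of residual blocks with strided max pooling and 1×1 projection
shortcuts, a configurable middle flow of identity-shortcut residual blocks,
and an exit flow ending in global average pooling and a softmax head.  A
`width_multiplier` scales every channel count and `middle_blocks` sets the
middle-flow depth; `xception_micro_config()` (multiplier 1/8, two middle
blocks) is the desk-scale preset used throughout the tests.

## Avg-TopK pooling

For a pooling window `w` and integer `K`, the pooled value is the mean of
the `K` largest window entries, so `K = 1` is max pooling and
`K = window²` is average pooling.  Worked 3×3 example:

```{r}
w <- matrix(c(1, 5, 2, 3, 8, 6, 4, 7, 0), nrow = 3, byrow = TRUE)
c(topk_mean(as.vector(w), 3), topk_mean(as.vector(w), 1),
  topk_mean(as.vector(w), 9))
```

Ties at the K-th value are resolved by row-major scan order.  Under same
padding only in-bounds cells participate and `K` is clamped to their
number, so border windows are never diluted by padding.  The backward pass
routes `upstream / K_eff` to each selected position — the exact gradient of
the top-K mean away from ties.  `replace_max_pooling()` performs the graph
surgery that swaps every `max_pool` node for an `avg_topk_pool` node with
identical window, stride and padding.

## Sparsity-guided pruning

Layer importance is measured as batch-averaged activation sparsity
`S(l) = (1/B) Σ_b #{a = 0} / |a|` over a profiling batch of `B = 16`
validation images (`profile_model()`; ReLU emits exact zeros, so the
default zero tolerance is 0).  The cut (`select_cut()`) is the candidate
with maximal sparsity — high sparsity is read as low importance — and
`truncate_at()` keeps the ancestor subgraph, `attach_classifier_head()`
adds a fresh global-average-pool + dense + softmax head, and
`prune_and_retrain()` re-initialises and retrains from scratch.

Two structural rules constrain the candidates.  First, a cut inside an
unmerged residual branch is rejected (it would silently drop the parallel
trunk); the error names the nearest valid cut points.  Second, in
separable-convolution backbones the candidates are restricted to
activations downstream of the first identity-shortcut residual merge: the
entry flow — the stem and the strided projection-shortcut blocks that form
the generic feature extractor — is never a cut point.  On the full-scale
backbone this restriction reproduces exactly the candidate set over which
the published cut points range.  At desk scale it matters more: small
models trained briefly on synthetic data show a nearly flat sparsity
profile (all layers near 0.5), so without the structural rule the argmax
can land in the entry flow and destroy the network.

On the full-scale backbone, truncating at the deepest published cut point
removes 30–40% of backbone parameters (the acceptance suite computes this
exactly); the claimed full-scale accuracy figures are *not* reproduced
here — they require the real dataset and long training.

## Class rebalancing

`resample()` implements SMOTE: each synthetic sample is
`x + λ (x' − x)` with `λ ~ U(0, 1)` and `x'` one of the `k = 5` nearest
same-class neighbours (Euclidean, brute force).  Strategy taxonomy
(`imbalance_strategy()`): `minority` raises only the smallest class to the
largest count; `not_minority` raises all but the smallest; `not_majority`
raises all but the largest; `multiplier` (k×) multiplies every non-majority
count by `k`, capped at the majority count.  `target_counts()` exposes the
arithmetic separately; three cells of the published 2×/3×/4× table are
arithmetically inconsistent with their own rule and are treated as
typographical errors — the package reproduces the consistent values.

The reference study applies SMOTE to deep-feature vectors of the pruned
model; `extract_features()` supports that space, while the end-to-end
image pipeline interpolates in pixel space so that the balanced set can
feed augmentation and retraining directly.

## Augmentation and training

`balance_with_augmentation()` equalises class counts by sampling random
rotation/shift/shear/zoom/flip transforms (nearest-neighbour resampling
and nearest-edge fill, `augment_config()`), recording a provenance
manifest.  Training (`train_model()`) uses Adam (`ε = 1e-7`), learning
rate 1e-3, batch size 16, at most 50 epochs, early stopping on validation
loss (patience 10, best-weight restore) and reduce-on-plateau (factor 0.1,
patience 3), with a 0.2 validation fraction split from the training data.
Weights are Glorot-uniform; batch norm uses `ε = 1e-3` and momentum 0.99.

One numerical choice deserves note: batch-norm running moments are stored
as zero-initialised exponential moving averages and de-biased by
`1/(1 − 0.99^t)` at inference (with an identity fallback before the first
update).  With identity-initialised EMAs, a momentum of 0.99 keeps the
running moments far from the true batch moments for the first several
epochs, which corrupts early-epoch validation losses and can trap
best-weight restoration at a meaningless epoch; de-biasing removes the
initialisation transient without changing the converged statistics.

Metrics (`evaluate_model()`, `compute_metrics()`) are support-weighted
precision/recall/F1 plus accuracy; weighted recall equals accuracy by
construction.

## Synthetic data

`generate_dataset()` draws seeded synthetic 8-bit RGB lesion-like images:
each of the seven classes (`nv`, `mel`, `bkl`, `bcc`, `akiec`, `vasc`,
`df`) has a fixed recipe of background tone, lesion shape irregularity,
colour palette and texture; a `difficulty` parameter in `synthetic_spec()`
scales the class separability.  The default per-class counts (6705, 1113,
1099, 514, 327, 142, 115; 10,015 images) emulate the study's imbalance.
The generator exists to exercise the pipeline deterministically — it is
not a substitute for dermoscopy data, and accuracy on it does not transfer
to real lesions.

## The pipeline

`run_pipeline(pipeline_config(...))` executes, in fixed order: data
generation/loading, an 80/20 split, baseline training, sparsity profiling
and pruning with retraining, SMOTE resampling (training split only),
augmentation-based equalisation, max-pool → Avg-TopK replacement, final
training and test evaluation.  Each stage derives its seed from the global
seed via `stage_seed()` and writes plain-text artifacts (graph JSON,
profile CSV, manifests, metrics JSON, history CSV, log); a failure aborts
with the stage name, leaving earlier artifacts in place.
`validate_artifact_json()` checks emitted JSON against the shipped
schemas.  A command-line entry point is installed at
`system.file("cli", "dermcnn", package = "dermcnn")`.

## Scope and limitations

All defaults target CPU-only desk scale: micro backbone (~192k
parameters), 32–64 px images, hundreds to a few thousand samples.  The
implementation does not attempt GPU execution, real-image preprocessing,
or the full-scale (20M-parameter, 299 px) training runs of the reference
study, and no claims are made about metric values beyond what the test
suite and acceptance script actually compute.
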