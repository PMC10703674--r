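---
title: "Segmentation-guided contrastive embeddings: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-guided contrastive embeddings: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic data generator
does and does not emulate, and the numerical and design choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` do not themselves compute.

## 1. The embedding model

A local 3D view is a cube of intensity voxels centered on a skeleton node
of one segment, masked by that segment's instance mask: voxels belonging
to other objects or background are set to the fill value. Masking is the
load-bearing idea — it injects the segmentation's knowledge of object
identity into the input, so the encoder describes *this* neurite, not the
surrounding neuropil. Views are cubic in voxel index space; with
anisotropic voxels (default 32 × 32 × 40 nm) the physical extent is
anisotropic too, which mirrors serial-section EM reality.

The encoder is a residual 3D convolutional trunk (ResNet-18 layout at
full scale), global average pooling, then three dense "bottleneck" layers
ending at the 64-dimensional embedding. During training a three-layer
projection head maps the embedding to 16 dimensions, and two losses act:

* **NT-Xent** on the projections, temperature τ = 0.1. Rows arrive as N
  interleaved positive pairs; for each example the 2N − 2 other examples
  in the batch are negatives. Cosine similarity makes the loss invariant
  to per-row rescaling.
* **Decorrelation** on the embeddings: the mean squared off-diagonal
  Pearson correlation between embedding dimensions over the batch,
  `L_dec = Σ_{i≠j} C_ij² / (d² − d)`. It is affine-invariant per
  dimension and bounded in [0, 1]. Dimensions with zero batch variance
  are defined to contribute zero correlation.

Positive pairs come from the same segment at skeleton path length
≤ 150 μm, sorted into four half-open distance buckets
(0, 2 500] , (2 500, 10 000], (10 000, 30 000], (30 000, 150 000] nm.
Buckets equalize the draw over distance scales; within a batch, segments
are drawn without replacement so each pair's negatives come from other
segments.

### Open choices made here

The source architecture description pins the trunk family, the three
bottleneck layers to 64-d, the three projection layers to 16-d, and the
total trainable-parameter count (33,737,824), but not the hidden widths.
The reference configuration in `encoder_config_full()` fixes them as:
standard trunk (7³ stem, batch norm with trainable scale/shift, no
convolution biases, 1³ projection shortcuts), bottleneck 512–512–64 with
biases, projection 112–96–16 with biases. This member of the (non-unique)
solution family keeps the canonical 512-wide bottleneck; the parameter
count reproduces exactly and is the acceptance check on the
reconstruction.

Other deliberately made choices, all configurable:

* **Decorrelation weight** `w_dec = 1`: the combined loss is
  NT-Xent + w_dec · L_dec; the source states the term was added but not
  its weight.
* **Optimizer**: momentum SGD (momentum 0.9) with a short linear warmup
  and cosine decay from a base rate of 0.2, linearly rescaled by the
  batch size relative to the 1,024-example reference batch. Only
  "a decay schedule starting at 0.2" is pinned externally; warmup+cosine
  is the conventional choice for this loss family.
* **Unordered pairs** are deduplicated ((a,b) = (b,a)); distance exactly
  0 (the same node twice) is excluded; when a segment has empty buckets,
  the draw is uniform over its non-empty buckets.
* **Fill value** 0 with intensities centered by the volume-wide mean, so
  "masked out" coincides with "mean gray".
* **Photometric jitter** defaults to ±10% contrast and ±0.1 brightness on
  the masked-in voxels only; reflections are per-axis with probability
  0.5. The supervised baseline swaps photometric jitter for random
  axis-aligned 90° rotations (one of the 24 proper orientations).

## 2. Inference, the store, and aggregation

Embeddings are computed at skeleton nodes resampled greedily at
~1,500 nm path spacing (root = lowest node id per component, a
deterministic tie-break), skipping segments below 1,000 voxels and nodes
whose center voxel is not owned by their segment (possible at rare voxel
collisions). The store is a tibble keyed by segment id and XYZ nm, with
columns `e0…e63`, round-tripping through sharded CSV at float precision
(`segment_id,x,y,z,e0,…` — the layout of the published embedding
releases; plain directories are used rather than zipped shards).

Aggregation takes the per-dimension mean over all store rows of the same
segment within path radius R of a center node and records `n_nodes` and
`R_max`, the farthest contributor's path distance. Nodes of other
segments never contribute — the mask semantics carried forward. All path
queries run on a weighted graph (Dijkstra via igraph) with Euclidean
edge lengths in nm; arc length along the skeleton is the natural reading
of "skeleton path length". Cross-component distances are infinite.

## 3. Classifiers and protocols

* **Linear probe**: multinomial logistic regression (`nnet::multinom`),
  the standard minimal readout of an embedding space.
* **ResNet-2**: two residual fully-connected blocks (default width 128)
  with a softmax head, trained with Adam; used on aggregated embeddings.
* **Label-efficiency subsampling** redraws a uniform subsample until
  every class holds ≥ 3 examples and ≥ 10% of the drawn sample. The
  "at least 10%" phrase is ambiguous in the source (10% of the sample
  vs. 10% of an equal share); it is read as *fraction of the drawn
  sample*, the stricter and simpler predicate, and both the fraction and
  the floor are arguments.
* **Rebalancing** upsamples each class cyclically to the majority count.
* **Cell-level cross-validation** splits cells 75/25 per class,
  `n_repeats = 10` times; training embeddings are drawn equally across
  classes (repeating minority examples), test sides are rebalanced by
  repetition, F1 is per-class then macro-averaged, and pooled confusion
  matrices are class-balanced after concatenating runs.
* **Class collapsing** merges subtype probabilities by summation before
  re-evaluation (e.g. all pyramidal subtypes onto one class).

## 4. SNGP and out-of-distribution detection

The OOD head spectrally normalizes the ResNet-2 hidden weights
(power-iteration estimate each step, rescale when the top singular value
exceeds 0.95) and replaces the output layer with a random-Fourier-feature
Gaussian process: `φ(x) = √(2/m)·cos(W h(x) + b)` with m = 1024 fixed
random features (length scale 2) and trainable class weights β. After
training, the posterior precision over features is the Gaussian-likelihood
Laplace form `P = I + Φ'Φ`, giving the per-example predictive variance
`σ²(x) = φ(x)' P⁻¹ φ(x)`: directions spanned by training data carry low
variance, unfamiliar inputs stay near the prior. This follows the cited
construction behind the method; the exact hyperparameters of the original
("BERT setting") are not printed there, so feature count, length scale,
norm bound and ridge are exposed as arguments with these defaults.

Uncertainty is Dempster–Shafer `u = K/(K + Σ exp h_k)` computed on
mean-field-adjusted logits `h_λ = h/√(1 + λσ²)`; λ = 3/π² for the OOD
protocol, λ = 2 in the partner cascade (both external specifications).
σ² is a single per-example scalar shared across that example's logits.
Thresholds are calibrated by scanning midpoints between sorted unique u
values on a set-aside half of the evaluation set, maximizing the
in-vs-out F1, ties to the smallest threshold.

## 5. The synthetic data generator

The generator emulates the four inputs of the real pipeline: an intensity
volume with dense instance segmentation and nm voxel metadata, exact
per-segment skeletons, label tables, and synapse tables. Cells are
persistent random walks (optionally branching) swept with spheres into
the voxel grid, first-writer-wins on collisions (logged as a count of
contested voxels); intensity inside each segment is a class-specific
mean + oriented sinusoid + noise, so classes differ jointly in caliber,
branching and texture; background is Gaussian noise around 0.45. Node
"subcompartment" labels follow the local tube radius regime (thin <
120 nm = axon-like, 120–280 = dendrite-like, > 280 = soma-like), with an
optional thick blob at each root so regimes mix within a cell. Synapses
are placed by ray-marching from skeleton nodes to the first foreign
segment within ~2 voxels of the tube surface.

Default study conditions: 128³ voxels at 32 × 32 × 40 nm (a ~4 × 4 × 5 μm
box), 18 cells round-robin over three classes, 6–12 μm of centerline per
cell, 250 nm node spacing, synapse density 0.25 per μm. Path lengths are
bounded by what the box can physically hold: the volume is comparable to
a single full-scale field of view, roughly a million times smaller than
the datasets the method targets.

What passing tests on this data do **not** show: realistic EM texture or
imaging artifacts (no section misalignment, no staining gradients), no
agglomeration errors beyond the deliberate "merged cell" construction
used by the uncertainty tests, and — most importantly — no separation
between the length scale of cells and of positive pairs. In these toy
volumes positive pairs routinely span a cell's entire 6–12 μm extent, so
the contrastive objective correctly collapses *within-cell* distinctions
(such as the radius regimes) that remain separable at the real scale,
where ≤ 150 μm pairs rarely cross subcompartments of mm-scale neurons.
For that reason the label-efficiency comparison in the acceptance suite
(probe on embeddings vs. fully supervised from voxels, at the smallest
admissible sample size of 3 examples per class) uses the per-node
*cell-class* task, the honest local-annotation analogue at this scale.

## 6. Numerical choices and degenerate inputs

* Batch norm uses per-channel batch statistics during training
  (ε = 1e-5, running-average momentum 0.1) and running statistics at
  inference, making inference deterministic given a checkpoint.
* NT-Xent exponentiates after subtracting the row maximum; zero-norm
  projection rows are an error rather than silently normalized.
* The decorrelation gradient flows through the mean, the standard
  deviation and the correlation (verified against finite differences in
  the tests); zero-variance dimensions contribute zero loss and zero
  gradient.
* Checkpoints carry the optimizer velocity, the RNG state and the
  learning-rate schedule position, so a restarted run reproduces the
  loss trace of an uninterrupted one. Refinement instead restarts the
  schedule over the new run (the schedule is part of what "training on a
  new dataset" means, not a property of the old run).
* Nearest-node ties break lexicographically by (x, y, z); resampling
  roots and traversal orders are fixed by node id; all stochastic
  procedures take explicit seeds.
* A divergent training step (non-finite loss) aborts with the step index
  and both loss components.
* Empty cases are first-class: zero cells, single-node skeletons, empty
  buckets, R = 0 windows, and segments absent from the store all have
  defined behaviour and tests.

## 7. Problem sizes used by the test suite

The suite trains toy encoders (33³ views, widths 8/16/32, bottleneck
32–32–64, projection 32–32–16) for 250–600 steps at 8 positive pairs per
batch on 128³ volumes, infers a few hundred embeddings, and runs the
classifier, OOD and partner protocols on those. These sizes are the
package's chosen desk-scale study conditions; the full-scale
configuration is exercised where it is cheap (parameter counting, shape
contracts). The 3-seed end-to-end recovery check, the 10-seed paired
label-efficiency comparison, and the per-class OOD rotations all run at
these sizes.

## 8. Known limitations

* No TEASAR-style skeletonizer: synthetic skeletons are exact by
  construction; real data enters through SWC files produced elsewhere.
* The CSV shard reader accepts plain directories, not zipped shard
  archives.
* Depth/lateral profiling of partner types is a generic 1-D histogram
  over a user-supplied axis; no anatomical coordinate transform is
  included.
* Training is single-threaded CPU R/C++; it is meant for method study
  and desk-scale validation, not for re-training on real volumes.
* UMAP-style manifold exploration is out of scope; `plot_embedding_pca()`
  offers a linear stand-in, and the cluster-then-inspect recipe can be
  reproduced with any external UMAP/k-means implementation on the
  exported store.
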