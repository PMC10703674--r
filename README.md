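# segclr

Self-supervised embeddings of local 3D morphology and ultrastructure for
segmented volumetric microscopy, with the downstream machinery that turns
those embeddings into biology: subcompartment and cell-type classifiers,
uncertainty-aware out-of-distribution (OOD) detection, and synaptic-partner
typing.

The package is aimed at connectomics practitioners who have an electron
microscopy volume with a dense instance segmentation and per-segment
skeletons, and want compact vector descriptions of every neurite fragment
without manual feature engineering or (much) ground-truth labeling. It also
ships a procedural generator of segmented tubular "cells" — with exact
skeletons, class labels and synapse tables — so the entire pipeline is
testable at desk scale.

## The method

**Contrastive embedding of masked local views.** Each training example is a
local 3D cutout (129 voxels per side at full scale; 33 at toy scale) whose
intensities are masked by the segmentation of the object at the center of
the field of view. Positive pairs are two views of the *same* segment
centered on skeleton nodes at most 150 μm apart along the skeleton path;
candidate pairs are binned into four path-length buckets with boundaries
0, 2.5, 10, 30 and 150 μm and drawn uniformly over non-empty buckets so
near and far pairs are equally represented. All other examples in the
batch — drawn from other segments — act as negatives. A 3D-convolutional
residual encoder (ResNet-18 layout) followed by three bottleneck layers
produces a 64-d embedding `z`; a three-layer projection head, used only
during training, maps it to a 16-d output `p` on which the
normalized temperature-scaled cross-entropy (NT-Xent) loss acts:

```
L_i = -log[ exp(sim(p_i, p_j)/τ) / Σ_{k≠i} exp(sim(p_i, p_k)/τ) ],   τ = 0.1
```

with cosine similarity `sim`. A decorrelation regularizer on the 64-d
embeddings discourages redundant dimensions:

```
L_dec = 1/(d² − d) · Σ_{i≠j} C_ij² ,
```

where `C` is the Pearson correlation matrix of embedding dimensions over
the batch and `d = 64`.

**Inference and aggregation.** After training, the projection head is
dropped. Embeddings are computed at skeleton nodes resampled to ~1,500 nm
path-length spacing over every non-trivial segment (≥ 1,000 voxels) and
stored keyed by segment ID and XYZ position. For cell-level questions,
embeddings are aggregated by the per-dimension mean over all nodes within
a path-length radius *R* (0–50 μm); `R_max`, the farthest contributing
node's distance, flags fragments too short to trust.

**Classifiers and uncertainty.** Linear probes (multinomial logistic
regression) read out what the embedding space carries; a shallow
two-module residual network ("ResNet-2") handles aggregated cell typing.
For OOD detection the ResNet-2 hidden layers are spectrally normalized
and the output layer is replaced by a random-Fourier-feature Gaussian
process (SNGP) whose Laplace posterior yields a predictive variance
σ²(x). Logits are shrunk by the mean-field rule `h_λ = h/√(1 + λσ²)`
(λ = 3/π² by default) and converted to a Dempster–Shafer uncertainty

```
u(x) = K / (K + Σ_k exp(h_k(x))) ,
```

which is 0.5 at all-zero logits and decreases as any logit grows.

**Partner typing.** Each synapse's pre- and post-synaptic fragment is
typed by finding the nearest embedding node in Euclidean space,
aggregating at 25 μm, and running an uncertainty cascade: fragments with
`R_max` < 2.5 μm or coarse uncertainty > 0.45 (or a glia call) are
`UNC`; inhibitory/excitatory fragments get a subtype only when the
subtype uncertainty is < 0.05 (`I-UNC`/`P-UNC` otherwise), and an
excitatory fragment is called thalamocortical only when that probability
exceeds the summed pyramidal subtype probabilities. Axonal-sorting
profiles bin typed synapses by path distance from the soma (20 μm bins)
and report per-bin excitatory/inhibitory ratios with mean ± s.e.m.
across cells.

## Worked example

```r
library(segclr)
library(dplyr)

# a small segmented volume: 9 tubular cells from 3 morphology classes
synth <- generate_synthetic(synth_config(volume_shape = c(96, 96, 96),
                                         n_cells = 9,
                                         cell_path_length_um = c(4, 8),
                                         seed = 401))
#> <segclr_synth> 9 cells, 13 synapses, 35436 voxel collisions (seed 401)

# positive-pair pools over the skeletons
pools <- enumerate_pair_pools(synth$skeletons)
count(pools, bucket)
#>   bucket     n
#> 1      1  1794
#> 2      2  1032

# a short contrastive run on 33^3 masked views
enc <- build_encoder(encoder_config_toy(), seed = 1)
#> <segclr_encoder> view 33^3, 3-stage trunk, 64-d embedding,
#>   64,456 trainable parameters (step 0)
ck <- train_encoder(enc, synth$volume, synth$skeletons, pools,
                    steps = 60, batch_pairs = 4, base_lr = 0.6, seed = 2)
glance(ck)
#>    step n_params embedding_dim final_loss
#> 1    60    64456            64       1.25

# embeddings at ~1,500 nm spacing, keyed by segment and position
store <- infer_embeddings(ck, synth$volume, synth$skeletons)
store[1:3, 1:7]
#>   segment_id node_id     x     y     z    e0    e1
#> 1          1       1 2345. 2581. 2783. 0.990  1.28
#> 2          1       7  998. 2258. 2371. 0.844  1.19
#> 3          1      13  352. 2768. 2192. 0.892  1.37

# aggregate at 5 um and read out the cell class with a linear probe
agg <- aggregate_store(store, synth$skeletons, R_nm = 5000) |>
  left_join(synth$labels, by = "segment_id")
ec <- grep("^e\\d+$", names(agg), value = TRUE)
fit <- train_linear(agg[, ec], agg$class_name, seed = 1)
macro_f1(agg$class_name, predict(fit, agg[, ec], type = "class"))
#> [1] 1
```

Even after a one-minute training run, the 64-d embeddings aggregated at
5 μm separate the three synthetic morphology classes perfectly
(macro-F1 = 1 here is on the training cells; the test suite evaluates
held-out segments, where the 3-seed median is also ≥ 0.9). The bucket
table shows that in a ~4 μm box only the two nearest distance buckets
(≤ 2.5 μm and 2.5–10 μm) are populated — the sampler draws uniformly
over whichever buckets exist.

A thin command-line front end over the same functions is installed at
`inst/cli/segclr.R` (`synth`, `pairs`, `train`, `infer` subcommands).

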