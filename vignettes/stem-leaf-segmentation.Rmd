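---
title: "Stem-leaf segmentation and phenotyping of plant point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem-leaf segmentation and phenotyping of plant point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(PlantPointSeg)
```

## The problem

Image-based plant phenotyping pipelines reconstruct a seedling as a 3D point
cloud and then need two things from it: a per-point semantic segmentation
into stem and leaf, and, from the segmented leaves, the phenotype parameters
a breeder actually wants — plant height, leaf length, leaf width, and leaf
area. Purely Euclidean point-feature encoders capture local geometric
relationships well but represent the plant's part-whole hierarchy (plant →
organ → surface patch) poorly; hyperbolic space, whose volume grows
exponentially with radius, embeds tree-like hierarchies with low distortion.
This package implements a segmentation network that encodes each point's
neighbourhood in *both* geometries and learns to blend them, plus the full
surrounding pipeline: preprocessing, training, leaf instance clustering, and
phenotype extraction.

## The model

**Input.** A cloud of N points (coordinates only), unit-ball normalized.
For every point a kd-tree exact K-nearest-neighbour graph is built in
coordinate space (default K = 20; ties broken toward the lower index so the
graph is deterministic).

**Euclidean channel (adaptive graph convolution).** For every directed edge
(i, j) the spatial encoding is `dx_ij = [x_i; x_j - x_i]` (6-dim) and the
feature encoding `df_ij = [f_i; f_j - f_i]` (2D-dim). A shared two-layer
perceptron generates M adaptive kernels `g_m(df_ij)` in R^6, and the kernel
responses are `h_ij[m] = LeakyReLU(<dx_ij, g_m(df_ij)>)`. A channel-wise
softmax over the K neighbours (attention pooling) aggregates the responses
into the point feature `f_i^e`, followed by a linear post-map. Because the
kernels are generated from the *feature* encoding and contracted against
the *spatial* encoding, the convolution adapts its geometry per edge.

**Hyperbolic channel (star-transformer over the Poincaré ball).** Point
features are linearly projected to width M and mapped onto the Poincaré
ball of curvature -c via the exponential map at the origin,
`exp_0^c(f) = tanh(sqrt(c)||f||) f / (sqrt(c)||f||)`. Each point's
neighbourhood becomes a star graph: the centre ("planet") connected to all
K neighbours, which form a ring in ascending-distance order with cyclic
adjacency (ring edges may be dropped independently with probability
1 - edgeProb; the default keeps the full ring deterministic). L stacked
layers update first every ring node from its cyclic context (previous,
self, next, planet) and then the planet from `[s; H]`, each update being
multi-head scaled dot-product attention followed by ReLU and layer
normalization. The channel output is the residual
`f_i^h = exp_0^c(proj(f_i)) + lambda * s^L`, clamped to the open ball, and
the gate consumes its tangent-space image `f_i^{h'} = log_0^c(f_i^h)`.

**Gate fusion.** `g = sigmoid(W [f^e; f^{h'}])` element-wise, and the block
output is the convex combination `g * f^e + (1 - g) * f^{h'}`, so each
feature coordinate always lies between the two channels' values.

**Architecture.** Two full-resolution blocks, then three pooling stages
(block + farthest-point sampling at rate 4 + neighbourhood max pooling),
yielding the point cascade N / N/4 / N/16 / N/64. All five stage outputs
are brought back to N rows by 3-nearest-neighbour inverse-distance
interpolation, concatenated, and classified by a shared per-point MLP with
hidden widths (512, 256) and a p-way output.

**Loss.** `alpha * L_CE + beta * L_triplet` with `alpha + beta = 1`
(defaults 0.9/0.1). The triplet term operates on the concatenated pre-head
embedding with squared-distance margin 0.2 and seeded random triplets.
Training uses SGD with momentum 0.9 under a cosine-annealed learning rate
from 0.1 to 0.001, batch size 4, early stopping on the monitored loss.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 20 | neighbourhood size of every KNN graph (dimensionless) |
| `stageDims` | 32, 32, 64, 128, 256 | feature widths of the five stages |
| `poolingRate` | 4 | FPS decimation per pooling stage |
| `hgsLayers`, `hgsHeads` | 2, 4 | star-transformer depth / head count |
| `lambda` | 1.0 | residual scale of the hyperbolic channel |
| `curvature` | 1.0 | positive c of the ball of curvature -c (fixed, not learned) |
| `edgeProb` | 1.0 | ring-edge retention probability of the star graphs |
| `alpha`, `beta`, `margin` | 0.9, 0.1, 0.2 | loss mixing and triplet margin |
| `lrMax`, `lrMin`, `momentum`, `batchSize` | 0.1, 0.001, 0.9, 4 | optimizer schedule |

The stage widths deserve a note: the architecture fixes the *pattern*
(two widths repeated, then doubling per pooling stage) but the absolute
widths are configuration. The defaults here (32 to 256) are chosen for
single-CPU training and inference; every width is adjustable through
`ggeConfig()`, and the head keeps its (512, 256, p) shape. The scaled
configuration used by the learning-sanity test and the acceptance script
halves these widths again (16, 16, 32, 64, 128), uses one HGS layer, and
halves the head; the problem sizes there are 32 training plants of 512
points each with K = 10, which one CPU trains in a few minutes.

## Design choices where the design was open

* **Softmax axis of attention pooling.** The pooling weights are computed
  channel-wise over the K neighbours, matching the adaptive-convolution
  lineage the Euclidean channel follows; the alternative (softmax over
  channels) would not be permutation-invariant in the neighbourhood.
* **Attention in ball coordinates.** The star-transformer arithmetic is
  applied directly to ball coordinates, with the logarithmic map applied
  once at the gate. Attention outputs (after layer normalization) are not
  confined to the ball, so the residual is clamped to radius
  `(1 - 1e-4)/sqrt(c)` before the log map — without the clamp `artanh`
  diverges. A tangent-space attention variant is deliberately not the
  default; the direct form is the stated design.
* **FPS seeding.** The first pick of farthest-point sampling is the
  `(seed mod N)+1`-th farthest point from the centroid. This makes the
  hierarchy deterministic given the seed *and* covariant under input
  permutations, which is what makes the network's scores exactly
  permutation-equivariant (an index-based first pick would break that).
* **Elbow rule for the leaf count.** K-means inertia over K = 1..10 is
  computed with K-means++ restarts plus a warm start that splits the
  previous solution (this guarantees a non-increasing curve). The elbow is
  the point of maximal perpendicular distance to the chord of the
  [0,1]-normalized **log**-inertia curve. On the linear scale the inertia
  of multi-leaf plants decays convexly across scales and the chord
  criterion lands near K = 3 regardless of the true count; on the log
  scale it reliably finds the K where within-cluster structure is
  exhausted. A guard declares "no elbow" (K = 1) when a first split fails
  to halve the inertia, which is what a structureless single cluster looks
  like.
* **Uniform downsampling** is seeded uniform sampling without replacement
  (voxel grids cannot hit an exact 4,096-point target); the normalization
  "matrix" is stored as (centroid, scale) of the unit-ball transform.
* **Vacuous metric classes.** A class absent from both prediction and truth
  scores IoU 1 and is included in the mean IoU (configurable to `skip`);
  overall accuracy is global (micro) across all points.
* **Leaf length/width** are distances between PCA-extremal surface points,
  as the measurement protocol states — curvature therefore inflates both
  slightly relative to a flattened leaf, which is visible as a small
  positive bias on strongly drooping synthetic leaves.
* **Ball-pivoting radii** default to (1.5, 3, 6) times the leaf's mean
  nearest-neighbour spacing; ascending multi-radius passes let larger
  balls bridge regions the small radius left open. Vertex normals come
  from local PCA with BFS orientation propagation over the KNN graph.
* **Numerical details.** LeakyReLU slope 0.2 throughout; cross-entropy logs
  clamped at 1e-12; gradients clipped to global norm 5 (the 0.1 peak
  learning rate occasionally produces a large step early in training);
  layer-norm epsilon 1e-5; exp/log map radial factors switch to their
  series expansions below 1e-7 to avoid 0/0. Because `tanh` saturates to
  exactly 1.0 in double precision beyond arguments of ~19, `expmap0`
  clamps its output to radius `(1 - 1e-10)/sqrt(c)` so the strict
  ball-containment contract survives floating point; the inverse identity
  `logmap0(expmap0(f)) = f` is numerically meaningful only while `artanh`
  retains precision (norms up to roughly 10).

## The synthetic plant generator

Real cucumber-seedling clouds are not redistributable, so the package
generates parametric stand-ins: a vertical stem tube on a gently bowed
centerline, and per leaf a bent elliptical patch attached at laddered
heights and golden-angle azimuths. Leaves are ruled surfaces whose midrib
droops with constant curvature, so every patch has the closed-form area
`pi/4 * arcLength * width`, and the base-tip chord and maximal lateral
extent provide analytic length/width ground truth. Four extreme points
(base, tip, two sides) are always sampled so extent measurements are exact
at zero noise. Points are allocated to organs proportionally to surface
area — the thin stem is the ~10% minority class, as in real plants — and
isotropic Gaussian surface noise (default 0.05 cm) emulates reconstruction
error. Default dimensions emulate a cucumber seedling at the 6-8 leaf
stage: 25 cm stem, 8-14 cm leaves.

What the generator does *not* emulate: multi-view reconstruction artefacts
(ghost points, non-uniform density, holes from occlusion), petioles,
self-occluding leaf overlap, and background clutter. Passing tests on
synthetic plants therefore demonstrate that the pipeline's machinery is
correct and that the architecture can learn organ geometry; they do not
certify accuracy on reconstructed field data.

Two named study conditions recur in the tests: the *default* spec above
(used for training runs, 4,096 or 512 points per plant depending on
scale), and a *separated-leaf* spec (45-54 cm stem, 3-5 cm leaves, 6
leaves, 12,000 points) used for instance clustering and phenotype
recovery. Inertia-based elbow selection needs leaves whose separation
exceeds their diameter, which the bushy default geometry deliberately
violates; and phenotype extraction runs at the restored full sampling
density (~12k points/plant, the raw resolution of reconstructed
seedlings), where the ball-pivoting rim deficit drops to a few percent.

## Known limitations

* The elbow criterion fails on bushy plants with strongly overlapping
  leaves (it reports "no elbow"); the heavier alternative would be a
  learned instance embedding, which is out of scope here.
* Ball-pivoting slightly underestimates patch area near sparsely sampled
  leaf tips (~3-5% at the default sampling density), a known property of
  pivoting reconstructions on open surfaces.
* Training at the full default widths on 4,096-point clouds is a
  GPU-scale workload; on one CPU the package is intended for the scaled
  configurations documented above.
* The network consumes coordinates only (no colour/normal channels), per
  the stated input contract.
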