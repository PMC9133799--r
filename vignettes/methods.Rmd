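---
title: "Methods: self-supervised image reconstruction and semantic decoding from voxel responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised image reconstruction and semantic decoding from voxel responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Paired fMRI datasets — images shown to a subject together with the evoked
voxel-response vectors — are small (hundreds to a couple of thousand
pairs), noisy, and span few semantic categories, while the space of
natural images is vast. `voxrecon` implements a two-network approach to
reconstructing seen images from voxel responses that works around this
data scarcity with *self-supervision on unpaired images*:

* an **encoder** $E$ maps an image $s$ to a predicted response vector
  $\hat r = E(s)$;
* a **decoder** $D$ maps a response vector $r$ to a reconstructed image
  $\hat s = D(r)$.

Training runs in two phases. Phase I fits $E$ on the paired data under
the fMRI loss

$$L_r(\hat r, r) = \alpha\,\mathrm{MSE}(\hat r, r)
  - (1-\alpha)\cos\angle(\hat r, r), \qquad \alpha = 0.9,$$

a convex mix of mean squared error and cosine proximity. Phase II freezes
$E$ and fits $D$ with mixed batches: a supervised term $L_D$ decodes
measured responses of paired samples and compares them to their images,
and a cycle-consistency term $L_{ED}$ pushes $D(E(s)) \approx s$ for
unpaired images $s$ that have no recorded responses at all. Because the
encoder is frozen, the cycle is forced through the response space — this
is what distinguishes the construction from an autoencoder. No class
labels enter training at any point.

Both image terms use the same composite image loss

$$L_s(\hat s, s) = L_{RGB} + L_{perceptual} + \lambda_{TV}\,TV(\hat s),$$

with every component normalized into $[0,1]$: $L_{RGB}$ is the mean
absolute pixel difference; $L_{perceptual}$ compares channel-normalized
feature tensors of a hierarchical backbone at all of its blocks through
cosine similarity, mapped to $\tfrac{1}{B}\sum_b (1-\cos_b)/2$; and the
total-variation term is the mean absolute neighbour difference, which is
exactly 1 for a binary checkerboard. The literature writes these
components only up to proportionality; the normalization constants above
are our concrete choice and keep the equal-weights default meaningful.
Reconstruction quality is insensitive to the exact balance; the TV weight
defaults to 0.1.

## Architectures

The **encoder** builds four parallel branches on backbone blocks 1–4.
Each branch applies batch normalization, a 3×3 convolution to 32
channels, ReLU, a resize to the branch grid, and batch normalization.
Branch grids are `side/4` for branches 1–3 and `side/8` for branch 4, so
at 112 px input the branch tensors are 28×28×32 and 14×14×32. A
*space-feature locally-connected* readout then stacks the 3×3
neighbourhood of every interior cell along channels (26×26×288 and
12×12×288 after trimming one boundary pixel), pools each stacked tensor
with a per-voxel spatial map (a learned receptive field, smoothed by a
total-variation penalty), weighs the 288 channels per voxel, and mixes
the four branch outputs with per-voxel non-negative weights initialized
at 1. All other weights are Glorot-normal. The branch resize is
implemented uniformly as ×2 average pooling (when the block grid is finer
than the branch grid) or nearest-neighbour upsampling (when coarser);
this reproduces the printed tensor shapes at every resolution divisible
by 8. An optional `nonneg_spatial_maps` switch clamps the spatial maps at
zero after each optimizer step for strictly non-negative pooling fields;
the default leaves them signed.

The **decoder** maps the response vector through an unshared
(locally-connected) linear layer to `base × base × base_channels` feature
maps (14×14×64 by default), applies three blocks of ×2 nearest-neighbour
upsampling, convolution and ReLU followed by group normalization (16
groups), and a final convolution with a sigmoid that keeps the output in
(0, 1); with the defaults the output is 112×112.

The **backbone** is a pluggable contract: any hierarchy of feature blocks
with non-increasing resolution works. The packaged default is a seeded
random-weight pyramid (5 blocks of 3×3 convolution, ReLU and ×2 average
pooling, 16 channels each). The method's mathematics — the losses, the
readout, the cycle — is agnostic to the backbone weights, and a seeded
random pyramid keeps the package fully self-contained and byte
reproducible; pretrained weights can be substituted through the same
contract, and with them the perceptual loss and the classification
embedding inherit their semantics. The same backbone serves four roles:
encoder branch inputs, perceptual loss, the perceptual-similarity
identification metric, and the classification embedding (block 4).

No deep-learning framework is used: layers carry hand-derived backward
passes (verified against central finite differences in the test suite)
and an Adam optimizer with milestone learning-rate drops. The reference
training recipe is Adam at $10^{-3}$ for 50 epochs with 90% drops at
epochs 20/30/35 (encoder) and 150 epochs with 80% drops every 30 epochs
(decoder), with 16 paired plus 16 unpaired samples per step; the
desk-scale studies below shorten this (see *Study sizes*).

## Semantic classification of reconstructions

A reconstruction is classified against a gallery of class centroids: each
class is represented by the mean backbone-block-4 embedding of up to 100
sampled images of that class, and classes are ranked by the Pearson
correlation between the reconstruction's embedding and each centroid
(deterministic ties by class order). The rank of the true class is the
*rank score* (1 is best); top-k and n-way accuracies (truth plus $n-1$
sampled distractors) derive from the same similarity table, with
bootstrap confidence intervals. Because the decoder was adapted to novel
categories only through unpaired images and perceptual consistency —
never through labels — this is category-free, and the gallery may include
classes never seen in any training stage.

## Evaluation tools

* **n-way identification**: a reconstruction is compared against its
  ground-truth image plus $n-1$ distractors under the perceptual
  similarity metric; the trial is correct when the truth is nearest.
  Distractor sets are seeded and fixed across compared methods; ties
  break toward the lower candidate index (logged, measure-zero for
  continuous metrics).
* **Noise ceiling**: per voxel, repeats are split into random halves,
  half-means are correlated across stimuli, Spearman–Brown corrected
  ($2r/(1+r)$), averaged over 50 seeded splits, and clipped to $[0,1]$.
  The exact recipe behind the published estimator is not fully specified
  in the source literature; this split-half/Spearman–Brown reading is the
  field's standard one and is documented here as this package's
  definition.
* **Prediction accuracy**: raw Pearson correlation between predicted and
  measured responses across stimuli, optionally divided by the noise
  ceiling where the ceiling exceeds 0.1 (ratios below that are flagged
  rather than reported).

## Population receptive fields

The primary estimator is gradient-based: the gradient of one voxel's
predicted response with respect to the input image is squared, averaged
over color channels, and normalized. The map is averaged over 3 random
probe images (suppressing the dependence of the ReLU activation pattern
on any single probe), smoothed with a Gaussian kernel ($\sigma = 3$ px),
raised to the 10th power, and its center of mass is the pRF center. A map
is *confined* when at least half of the preprocessed mass lies within
15% of the image side from the center; non-confined voxels are screened
out of retinotopy summaries, mirroring the practice of discarding
spatially incoherent maps. Eccentricity and polar angle convert the
center to visual-field coordinates given a configured field of view
(0 at the right horizontal meridian, counterclockwise positive).

The secondary, weight-based estimator visualizes learned weights
directly: for the encoder, the squared per-voxel spatial maps averaged
across the branches sharing the finest grid (the `side/8` branch has too
few cells to express a center); for the decoder, the per-location mean
squared input-layer weights. In our trained models the weight-based
encoder maps are markedly less spatially coherent than the gradient maps:
the network is free to realize a localized input–output function through
spatially extended, mutually cancelling weight patterns, and batch
normalization absorbs map offsets, so nothing forces the raw spatial map
itself to resemble the voxel's receptive field. The gradient method
measures the function the network actually computes and is therefore the
method of record here; the same preference is expressed in the source
method's own analyses.

## The virtual subject and what it does (not) emulate

All tests run against a procedural **virtual subject**: each voxel has a
Gaussian pRF (center uniform within the central 70% of the field, width
$\sigma$ drawn from 8–16% of the image side), a unit-norm tuning vector
over a fixed 8-filter bank (three color-deviation channels, four oriented
Sobel edge-energy channels, one local-contrast channel), a gain
calibrated so the clean signal has unit standard deviation over a probe
stimulus set, and i.i.d. Gaussian repeat noise $\sigma_n$ in signal-SD
units. The pRF width range matters: population receptive fields in
parafoveal early visual cortex are a sizeable fraction of a typical
~10° stimulus field, and widths far below the encoder's effective
feature resolution are not recoverable by any readout of this
architecture — a documented limitation, not a target regime.

Stimuli are anti-aliased parametric scenes whose class is a cell of a
shape × color × texture grid (5×5×4 = 100 classes): each image holds 1–2
compact instances of the class shape plus 2–3 distractor shapes with
random attributes, all scattered across the field, over a mildly jittered
gray background, quantized to the 8-bit grid so PNG round trips are
exact. The clutter is essential: class-defining content recurs globally
while local content varies independently across locations, and without
such independent local variation voxel receptive fields are not
identifiable from paired data at all (verified during development with an
oracle ridge regression). The default benchmark mirrors the structure of
real paired-fMRI datasets at desk scale: 96 paired training stimuli from
12 classes, 16 test stimuli (8 repeats) from 8 disjoint classes, and
2000 unpaired images from 80 further disjoint classes, with all three
class sets pairwise disjoint.

The simulator does **not** model hemodynamics or temporal structure,
voxel-to-voxel noise correlations, cortical geometry, or the actual SNR
profile of any scanner; passing its tests demonstrates that the
algorithms are implemented correctly and behave as the method predicts
under a known ground truth, not that any particular real dataset would
yield a given accuracy.

## Study sizes and numerical choices

The shipped studies are sized for minutes on one CPU:

* *Benchmark study* (self-supervision benefit): 100 voxels, 32 px,
  $\sigma_n = 0.5$ (a deliberately low-SNR regime; published voxel
  noise-ceiling medians for this kind of data sit near 0.6), spec
  defaults 96/16×8/2000, encoder 15 epochs at Adam $3\times10^{-3}$ with
  90% drops at 10/13, decoder 10 epochs with an 80% drop at 7, 16+16
  batches. The self-supervised and supervised-only arms share seeds,
  schedules and distractor sets.
* *pRF recovery study*: the default subject (200 voxels, 64 px,
  $\sigma_n = 0.25$) with 600 paired stimuli and 25 encoder epochs,
  training stimuli drawn from 60 classes (diverse mapping stimuli); the
  noise sweep ($\sigma_n \in \{0, 0.5, 1\}$) uses 50-voxel, 32-px
  subjects with 600 stimuli and 20 epochs — below roughly 400 stimuli
  the encoder sits under the recovery threshold at every noise level and
  no trend is measurable. Shift augmentation stays on: disabling it lets
  the encoder fit the repeat noise and destroys map localization even as
  the training loss improves.
* The learning rate $3\times10^{-3}$ (rather than the reference
  $10^{-3}$) compensates for the shorter schedules; the milestone-drop
  shape is kept.

Other numerical choices: $\varepsilon = 10^{-8}$ for zero-norm channel
vectors in the perceptual terms (degenerate cosines are defined as 0);
anisotropic mean-absolute total variation; nearest-neighbour upsampling
in the decoder; per-branch batch-norm statistics; cosine of a zero
response vector defined as 0; Adam $\beta = (0.9, 0.999)$,
$\varepsilon = 10^{-8}$, no weight decay; shift augmentation defaults to
3 px at 112 input, scaled proportionally; all randomness flows from one
root seed split into named substreams. Pixel coordinates are 0-based
(row, col) with the origin at the top-left; degrees of visual angle are
measured from the image midpoint.

## Known limitations

* The random-weight backbone gives the perceptual loss and the embedding
  a generic, untuned notion of similarity; with pretrained weights the
  semantic claims would be stronger.
* At this desk scale the self-supervised and supervised-only decoders
  perform near-identically. A diagnostic experiment makes the reason
  precise: augmenting the supervised decoder with thousands of *oracle*
  pairs (perfect responses from the generative model) does not improve
  identification either, so the decoder is limited by the information in
  the voxel responses, not by training data. The benefit of unpaired
  cycle-consistency training appears in the data-limited regime created
  by natural-image complexity together with semantically structured
  pretrained features; the procedural stimulus space here is compact
  enough that 96 paired samples already cover it. The framework passes
  every mechanical check of the training scheme (loss decomposition,
  frozen encoder, exact degradation to the supervised baseline with an
  empty pool), but the performance ordering itself should be expected
  only on rich natural-image data.
* Weight-based encoder pRF maps are unreliable here (see above); rely on
  the gradient method.
* Training on unpaired *responses* (the converse of unpaired images) is
  intentionally not implemented, matching the source method's final
  design.
* The CLI covers the pipeline stages (`simulate`, `train-encoder`,
  `train-decoder`, `reconstruct`, `classify`, `evaluate`, `prf`) but is a
  thin veneer; programmatic use through the package functions is the
  primary interface.
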