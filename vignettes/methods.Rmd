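---
title: "Models and methods in clusterDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in clusterDx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterDx)
```

clusterDx implements two desk-scale diagnostic pipelines that share one
pre-processing primitive: a chunked, merge-based k-means. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic generators do and do not emulate,
and the design decisions taken where the underlying procedure left the
choice open.

## Chunked k-means

The clustering is Lloyd's algorithm reorganised as a coordinator/worker
loop. The n rows are shuffled under the configuration seed and split into
`nChunks` contiguous blocks whose sizes differ by at most one. Each round,
every worker — a pure function of its block and the current global
centroids — assigns its block to the nearest centroid (Euclidean distance,
ties to the lowest index) and computes local per-cluster means and counts.
The coordinator merges local centroids by count-weighted averaging; when a
single worker owns a cluster its centroid is taken verbatim, which makes a
one-chunk run bit-identical to textbook sequential Lloyd iteration rather
than merely numerically close. The loop stops when the maximum Euclidean
centroid displacement falls below `shiftThreshold`, at an exact fixed
point (displacement zero, so that a zero threshold cannot force vacuous
rounds), or at `maxRounds`.

Because workers share no mutable state, the result depends only on
`(data, config)`; running the blocks concurrently, sequentially, or in any
order cannot change it. This is the portable contract that replaces
device-specific dispatch queues.

Parameters: `k` (clusters; 2 for tabular pre-processing, 5 for pixel
quantization — see below), `shiftThreshold` in feature units (default
1e-6, i.e. effectively "run to the fixed point" on unit-scaled data),
`maxRounds` (100), `nChunks` (1), `seed`. Empty clusters are re-seeded to
the point farthest from the cluster's previous centroid — a standard
repair that keeps exactly k clusters alive; when no previous centroid is
available the global data mean is the reference.

## Tabular pre-processing

The stage order is: mean imputation → min–max normalization → k-means
(k = 2) → outlier flagging → cluster-feature augmentation. Clustering
requires complete, comparably scaled features, which fixes the first three
positions.

* **Imputation** replaces each missing cell with its feature's observed
  mean. A fully missing feature is an error, not a guess.
* **Normalization** maps each feature by (x − min)/(max − min); constant
  features map to 0. The recorded ranges are reapplied to new data.
* **Outlier flagging** scores each row by its Euclidean distance to its
  assigned centroid and flags rows beyond the `q` = 0.99 quantile of those
  distances. The underlying procedure names the effect (outlier
  identification via clustering) without fixing a rule; the
  assigned-centroid distance quantile is the simplest rule faithful to
  that description. Flagged rows are dropped by default (`dropOutliers`).
  After a drop, the min–max scaling is recomputed and the cluster model
  refitted on the retained rows: a far-field outlier would otherwise
  define the feature range and squash the informative values into a
  narrow band — the distortion the removal step exists to prevent.
* **Augmentation** appends k one-hot cluster-membership indicators
  (default), or replaces the features with the k distances to the
  centroids (`mode = "centroids"`, the dimensionality-reduction reading of
  "centroids as new features"), or both. The distance embedding is a mode,
  not forced, because the source description is ambiguous between the two
  readings.

## Logistic regression and the chunked ensemble

The classifier is plain binary logistic regression fitted by full-batch
gradient ascent on the Bernoulli log-likelihood. Two numerical points:

* `logregGradient()` returns the textbook sum-form gradient
  Σᵢ (yᵢ − f(zᵢ)) xᵢⱼ; the update inside `fitLogReg()` divides it by n so
  that the default learning rate α = 0.1 behaves identically across
  sample sizes (features are assumed unit-scaled, as the pre-processing
  guarantees). The source's update rule is written as descent on the
  likelihood while the text states likelihood maximization; ascent on the
  log-likelihood is the only self-consistent reading and is what is
  implemented.
* "Error" for the convergence check is the mean negative log-likelihood;
  iteration stops when its absolute change drops below `tol` = 1e-8 or at
  `maxIters` = 500. Probabilities are clipped to [1e-12, 1 − 1e-12] inside
  the likelihood only, never in predictions. The sigmoid is evaluated in
  the numerically safe branch for each sign of z, so ±710 does not
  overflow.
* Weights initialize uniformly in [−0.01, 0.01] under the seed.

The ensemble splits the data 70/30 (validation carved as 20% of the
training share — the source mentions a validation set without a fraction),
partitions the training set into `nChunks` balanced chunks, fits one
member per chunk, and combines predicted probabilities as a convex
mixture. Weights are proportional to the validation metric (accuracy by
default, rank-based AUC as the alternative); proportional normalization is
the simplest rule consistent with "weights based on validation
performance". All-zero metrics fall back to uniform weights. Refinement is
a deterministic hill climb: each round tries scaling every weight by 1.1
and by 0.9 (renormalizing), keeping only strict improvements of the
validation metric, and stops after a no-improvement round or
`refineRounds` = 20; the "desired level of performance" stopping target is
not quantified in the source, so no-improvement is the default rule. With
one chunk the ensemble is exactly one logistic model — the package tests
assert prediction-level identity, not approximation. Data parallelism only;
model or hybrid parallelism is out of scope.

## Image quantization

`clusterPixels()` clusters intensities only — one-dimensional k-means —
because the five "gray-scale stages" of chest radiographs are an intensity
phenomenon; spatial coordinates never join the feature vector. Labels are
canonicalized darkest-first so they are stable across runs, and the
per-cluster mean intensities are reported ascending. Initial centroids are
k *distinct intensity values* sampled under the seed rather than k pixel
rows: plateau-heavy images make duplicate row-sampled centroids likely,
and duplicate initial centroids can only lose clusters. When an image has
fewer than k distinct intensities, k is reduced with a warning. A
consequence worth knowing: on a noise-free image with exactly k distinct
levels the initialization is a permutation of those levels and recovery of
the level partition is exact by construction.

`renderClustered()` replaces each pixel with its cluster's mean (rounded
to the bit depth), producing a k-level quantization — the "clustered
image". `removeOutlierPixels()` replaces pixels deviating more than t = 3
cluster standard deviations from their cluster mean; the rule's shape
(t·σ about the cluster mean) is a design choice, as the source names only
the effect. `resizeNormalize()` performs corner-aligned bilinear
interpolation (output corners sample input corners exactly) to
`side` = 640 and min–max scales to [0, 1]. The pipeline order is cluster →
outlier removal → render → resize/normalize. Region features (area,
centroid, bounding box, mean/variance, aspect ratio) and a two-channel
stack (normalized intensity + label/(k−1)) are available for downstream
feature extraction; the channel inverts losslessly to the label map.

Which representation feeds a detector — the rendered clustered image, the
two-channel stack, or the raw image — is configurable
(`image.detectorInput`), with the clustered image as default.

## Detection geometry

The grid splits the image into S×S half-open cells of side imageSide/S;
the cell containing a box's center is responsible for it, with boundary
points assigned to the higher-index cell and the far image edge closed
into the last cell. Box encoding follows the cell-relative convention *as
stated by the source*: bx, by are the center offset within the owning cell
in [0, 1], and **bw, bh are measured in cell sides, not image sides**.
This differs from common practice (classic formulations scale width and
height to the image); `decodeBox()` inverts it exactly, and all loss
computations use the same convention, so the choice is internally
consistent. Confidence is the product Pr(class|obj) × Pr(obj) × IoU; at
inference, where no ground-truth IoU exists, decoded detections carry
conf = Pr(obj) × max class probability, and the three-factor form is
exposed separately for evaluation.

Non-maximum suppression is greedy and per-class: drop detections with
objectness below `objThresh` (default 0.5, the low end of the customary
0.5–0.7 range), keep survivors in confidence order (ties by input
position), and suppress later same-class detections whose IoU with a kept
one exceeds `iouThresh` (0.5). The package tests pin the greedy scan to an
exhaustive pairwise-suppression reference on random fixtures.

Anchor priors are derived by clustering ground-truth (w, h) shapes under
the 1 − IoU distance of co-centered boxes — Euclidean distance would
conflate scale with shape — using the same Lloyd iteration scheme as the
main clustering, and are reported area-ascending. The detection loss
matches each truth box to its owning cell and highest-IoU anchor (the
matching rule is a design choice; the source states the loss components
but not the matching), then sums a localization MSE over the four encoded
coordinates and the mean cross-entropy of class probabilities against the
one-hot truth, so uniform probabilities over C classes score exactly
log C per object.

`detectAndFlag()` accepts any backbone mapping an image to an
S×S×A×(5+C) tensor. The full convolutional backbone of a production
detector (and pretrained weights, GPU training, augmentation schemes) is
out of scope; instead `trainReferenceBackbone()` provides a tiny trainable
reference predictor for synthetic imagery: per cell it computes mean, max
and standard deviation of the cell's pixel block, fits the package's own
logistic regression to predict whether the cell overlaps a lesion, and
predicts each positive cell's box as the mean cell-relative encoding of
the training lesions. Overlap labels, not center-ownership labels, are
used for the scorer because a lesion brightens every cell it touches —
the intensity features carry overlap information, and center-labelled
training leaves neighbouring lesion-covered cells as unlearnable
false negatives (grid responsibility still governs encoding and loss
matching). The scorer's learning rate defaults to 20: its three features
live in [0, 1], positives are rare, and a 200-step budget needs large
steps to reach calibrated probabilities. S = 7, three anchors and two
classes are configuration defaults, not claims about any experiment.

## Synthetic generators

`genTabular()` draws a Gaussian mixture (default two unit-variance
components whose means sit `separation` = 2 standard deviations from the
origin on distinct axes), then labels rows by the logistic mechanism
y ~ Bernoulli(sigmoid(w0 + w·x)) with defaults w0 = −1, w = (2, −3) —
chosen so the Bayes accuracy is high but not trivial. Missing cells
(5%) and far-field outlier rows (1%, shifted ~25 units) are injected
after labelling, so the label mechanism stays purely logistic and
parameter recovery is well-defined. Per-cluster logistic offsets are
deliberately absent for the same reason.

`genImages()` builds side = 64 images of five horizontal intensity bands
(levels spanning 15–80% of the dynamic range) plus Gaussian noise
(σ = 2), and with probability `lesionRate` one to three bright elliptical
lesions with recorded bounding boxes. Lesions are *brighter than every
band* (95% of the range) by design: that guarantees they form their own
intensity cluster, which is exactly the k = 5-bands-versus-lesion
interaction the pipeline is meant to surface.

What the generators do **not** emulate: real radiographic texture,
anatomy, acquisition artefacts beyond isolated hot pixels, DICOM
metadata, or the class-imbalance profiles of public datasets. Passing
tests therefore demonstrate correctness of the algorithms and their
interactions under the stated statistical structure — not clinical
performance.

## Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path: 600-point mixtures for the clustering
comparisons, n = 5000 for logistic parameter recovery, n = 2000 for the
end-to-end tabular pipeline, 64×64 images with a 60-image training set
and a 40-image held-out set for the flagger. All randomness flows from a
single seed expanded per stage by a polynomial hash of the stage name
(`deriveSeed()`), so adding a stage never perturbs earlier stages, and
identical configuration yields byte-identical outputs.

## Known limitations

* The tabular arm is binary-classification only; no regularization or
  second-order optimizer is provided, as neither belongs to the procedure
  being implemented.
* PNG output is written at 8-bit depth (16-bit files are read and
  processed at full depth).
* The outlier-flagging quantile rule assumes outliers are rare relative
  to `1 − q`; heavy contamination would need a robust-location variant.
* k-means on intensities inherits Lloyd's local-optimum behaviour on
  noisy images; the distinct-value initialization removes the degenerate
  duplicate-centroid case but not local optima in general.
* The reference backbone is a validation instrument for the geometry and
  the flagging logic, not an object detector for real radiographs.
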