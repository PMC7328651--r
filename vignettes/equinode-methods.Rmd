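---
title: "Detecting stem nodes and classifying Equisetum hybrids from specimen images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stem nodes and classifying Equisetum hybrids from specimen images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equinode)
```

## The problem

*Equisetum hyemale*, *E. laevigatum*, and their widespread sterile hybrid
*E. ×ferrissii* are routinely confused in herbarium collections. The most
informative macroscopic character is the nodal leaf sheath on the aerial
stem: in *E. hyemale* mature sheaths are prominently cross-banded (a dark
stripe near the sheath base, an ashy white-tan zone above it, and a dark
rim), while in *E. laevigatum* sheaths are mostly green with a single
narrow black rim. The hybrid tends to combine both looks along a stem —
hyemale-like sheaths toward the base, laevigatum-like sheaths toward the
apex.

A single end-to-end image classifier is hopeless at realistic annotation
budgets: pressed specimens vary enormously in layout, color and stem count
(large intraclass variation) while the taxon signal hides in small node
patches (small interclass differences). `equinode` therefore follows a
two-stage design that mirrors how an expert works:

1. **Detect** aerial stem nodes anywhere on the sheet and type each one as
   hyemale-like (**H**) or laevigatum-like (**L**); optionally a third
   class **F** for nodes of hybrid images. Node type labels for training
   are *proxies*: every node annotated in an *E. hyemale* image counts as
   H, every node in an *E. laevigatum* image as L — no per-node typing by
   the annotator is needed.
2. **Classify** the whole image from summary statistics of the detections:
   the mean score of the ten top-scoring H detections (`a_H`) and likewise
   for L (`a_L`, plus `a_F` in three-type mode). A pure *E. hyemale* sheet
   should give high `a_H` and low `a_L`, a pure *E. laevigatum* sheet the
   reverse, and a hybrid sheet substantial values of both. Simple
   classifiers — multinomial logistic regression, a shallow decision tree,
   k-nearest-neighbor with k = 5 — operate in this 2-D (or 3-D) feature
   space.

## The detector

The detector is a single-stage anchor-grid ("multibox") design. A grid of
sample points with pitch 30 px — the size of the smallest object sought —
is laid over the image; each point carries 36 candidate boxes (6 sizes in
geometric progression from 30 to 120 px × 6 aspect ratios from 1/3 to 2).
Every anchor receives a class score over {background, H, L(, F)} and four
box-offset regressions (center shifts scaled by the anchor size, log size
ratios).

The reference pipeline at archive scale uses an SSD with a VGG16 backbone;
that architecture is defined by its contract (anchors, joint
classification + localization, overlap suppression), not by the backbone.
`equinode`'s desk-scale detector keeps the contract and replaces the
learned convolutional features with fixed mean-pooled grid features: each
anchor's pixels are pooled into a 6 × 4 grid of per-channel means (24
cells × 3 channels + intercept = 73 features), computed in O(1) per cell
from a summed-area table. The head is linear per anchor shape — each of
the 36 (size, ratio) combinations owns its own classifier and offset
regressor, exactly as an SSD output layer dedicates separate filters to
each anchor shape. The 6 × 4 grid (finer vertically than horizontally)
resolves the horizontal banding that distinguishes the two sheath types.

Training minimizes the standard multibox loss: softmax cross-entropy over
anchors plus smooth-L1 on the offsets of positive anchors, normalized by
the positive count. Positive anchors are those with IoU ≥ 0.5 against a
ground-truth box, plus each ground truth's single best anchor (a contested
anchor goes to the higher-IoU ground truth). Background anchors enter via
hard-negative mining at 3:1 against positives; positives additionally
carry weight 3 in the classification loss to offset the residual skew.
Optimization is plain mini-batch gradient descent: batch size 8 images,
fixed learning rate 1e-4. Three numerical choices make the fixed learning
rate workable for a linear head:

* **Input standardization.** Pooled features are standardized per feature
  (center and spread estimated once from sampled anchors of the training
  images) and scaled so that one gradient step moves a logit by order one.
  This is the analogue of the mean-subtracted-pixel normalization of deep
  detector inputs, and it is stored with the model.
* **Background prior initialization.** The background bias starts at
  `log(p/(1-p) * K)` with p = 0.9, so the model begins by predicting ~90%
  background everywhere instead of spending hundreds of iterations
  rediscovering that most anchors are background.
* **Early stopping on validation loss.** The multibox loss on held-out
  validation images is evaluated every 25 iterations; training stops at
  the iteration cap or after 5 checks without improvement, and the
  best-validation checkpoint is returned.

Each training image is augmented on the fly: rotation by a random angle
about the image center (bilinear, border filled with the mean image
color) followed by a random 500 × 500 crop, with boxes mapped to the
axis-aligned hulls of their rotated corners and dropped when less than
half their area stays visible. Evaluation images are processed whole —
the anchor grid simply extends to the image size.

At detection time every anchor is scored, the per-anchor best type and its
softmax probability form a candidate detection, candidates below the score
threshold (default 0.3) are dropped, boxes are refined by the regressed
offsets, and greedy overlap suppression (IoU > 0.5 against a higher-scoring
kept box) removes duplicates. Ties in score break deterministically by
box coordinates, so suppression is invariant to input order.

## The synthetic benchmark

Real digitized sheets cannot ship with a package, so `equinode` generates
synthetic pressed specimens that preserve exactly the contrasts the
pipeline exploits, with ground truth known by construction:

* paper-colored background with additive Gaussian noise (sd 0.02);
* 2–4 gently curved green stems per 700 px sheet, maximum tilt 0.02–0.12
  radians;
* 8–14 nodes per stem at regular intervals, rendered as 36 px patches:
  H nodes as a light tan field with two interior dark bands (basal stripe
  and rim), L nodes as a green field with one narrow dark rim, both with
  per-node jitter in band position, width, hue, and pixel noise;
* taxon rules: *hyemale* sheets carry only H nodes, *laevigatum* only L;
  *ferrissii* nodes are H with probability interpolated linearly from 0.9
  at the stem base to 0.1 at the apex (`hybrid_gradient`). The linear form
  is the simplest monotone model of the qualitative basal-to-apical
  gradient; a quantitative H:L ratio for real hybrid stems is not
  established, so these defaults are configuration, not biology.

The emulated study design is 36 images per taxon (108 total), split
54/24/30 into training, validation and test, stratified by taxon.

What the generator does *not* emulate: internode texture variation,
injured or overlapping nodes, strobili entering the detector (they can be
rendered but are never detected, matching the reference protocol's
exclusion), faded specimens, labels/stamps on sheets, and the full
within-taxon morphological variability of real collections. Passing the
package's end-to-end tests therefore demonstrates that the pipeline's
machinery — proxy labeling, detection, score statistics, classification,
evaluation — works as specified on data with the right structure; it does
not certify archive-scale accuracy on real digitized collections.

## Statistics and classifiers

Per image and node type, detections are sorted by score and the top 10
averaged (`top_k_mean`); fewer than 10 available means averaging what
exists, and none at all yields 0 — "no evidence of this type" — keeping
the feature space bounded (zero-padding to exactly 10 is available as a
flag for sensitivity analysis). The ratio `a_H / a_L` and the top-10
standard deviations are implemented behind the `variant` argument for the
ablation narrative; the means are the default because they are what works
best. Score quantization (×10, rounded half away from zero, giving the
0–10 display scale where 0.73 shows as 7) is display-only and never enters
any computation.

The classifiers are deliberately small-sample tools: multinomial logistic
regression with mild L2 (weight decay 1e-3, since unregularized fits need
not converge on separable data), an rpart decision tree (Gini, depth ≤ 3,
minimum leaf 2 — strong regularization for ~54-point training sets), and
an exact k-nearest-neighbor (Euclidean, k = 5; vote ties go to the tied
class with the smaller mean neighbor distance, then to the fixed taxon
order). No feature scaling is applied: `a_H`, `a_L`, `a_F` already share
the [0, 1] scale.

## Evaluation

Detections are matched greedily to annotations in descending score order,
each detection claiming the unmatched annotation of highest IoU ≥ 0.5.
Matched pairs feed the node-type confusion matrix (true type = the proxy
type of the image's taxon; hybrid images are excluded in two-type mode,
where their nodes have no defined truth); cross-type accuracy is the trace
over the total. The same machinery renders the reported count grids of
the reference experiments and recomputes their derived numbers (272
matched nodes and 98% two-type accuracy; 87%, 36-of-229 H↔F confusion and
6-of-96 laevigatum-column errors in three-type mode; 27/30 = 90% image
accuracy for both the 5-nn and tree classifiers). False positive and
negative counts are reported but advisory only: on real sheets annotation
is incomplete and many unmatched detections are genuine nodes, which is
also why false-negative rates are not a headline metric. Percentages are
rounded half away from zero, matching the display convention.

On the tables' orientation: the reference grids label rows "true node
type" and columns by *image* type; the caption arithmetic (column sums,
e.g. 6-of-96 for the laevigatum column) is what the helper
`label_error_count()` reproduces. All other derived numbers are invariant
to transposition, so the ambiguity is documented rather than resolved.

## Problem sizes, determinism, limitations

The shipped tests and the acceptance script run the full pipeline on the
emulated design (108 images of 700 px, 500 px training crops, up to 2000
training iterations with early stopping typically engaging much earlier on
this synthetic data). Detection and training kernels (rotation,
summed-area tables, feature pooling) are compiled; everything else is
plain R. All randomness flows from explicit seeds through one restored
RNG context per call — fixed seeds reproduce images, splits, training
trajectories and reports byte for byte; nothing touches the global RNG
state of the session.

Known limitations, deliberate:

* the linear per-shape head is weaker than a deep backbone; on noisy or
  low-contrast sheaths its recall drops before its cross-type accuracy
  does (missed nodes are cheap for image-level classification; mistyped
  nodes are not);
* anchor sizes/ratios are configuration (the reference counts are stated,
  their values are not);
* no stem skeletonization or node-position features — the relative
  position of nodes along stems is known to carry signal for hybrids and
  is exactly the information the per-image score averages discard;
* strobilus detection is out of scope (too few strobili to train on).
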