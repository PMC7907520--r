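---
title: "Radiomics feature mapping and SE-CNN classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics feature mapping and SE-CNN classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiomap)
```

## The problem

Whether a lung adenocarcinoma carries an EGFR mutation decides whether
EGFR-targeted therapy can be used, but the assay requires tissue. CT
radiomics offers a non-invasive surrogate: hundreds of quantitative
features (lesion shape, first-order intensity statistics, and
GLCM/GLDM/GLRLM/GLSZM texture families, each computed on the original
image, its eight wavelet decompositions, and Laplacian-of-Gaussian filtered
images at several scales) that correlate with tumor biology. Classical
machine-learning models consume a few dozen such features; this package
implements a hybrid strategy instead — keep the interpretable, named
features, but hand many of them (784) to a small convolutional network by
arranging them as an image.

## The pipeline, stage by stage

### Feature catalog and tables

Features are named `"<channel>_<group>_<Metric>"`; the catalog is the cross
product of 12 image channels (original, 8 wavelet, 3 LoG) with the five
intensity/texture groups, plus shape features on the original channel only.
The per-group metric roster is configurable because extractor versions
differ in their exact rosters; the taxonomy, not the total count, is what
the pipeline relies on. Feature tables are strict: unique ids and names,
no missing and no non-finite values. Patients whose features could not be
extracted are expected to be excluded upstream, so loading *rejects* rather
than imputes.

### Selection

Features are scored by random-forest mean-decrease-impurity importance
(Gini), normalized to sum to one, and ranked with alphabetical
tie-breaking. Two conventions matter:

* **Split hygiene** — importance is computed on the development cohort
  only. The API takes a table already restricted to that split; the
  held-out test patients never influence which features are selected.
* **Column-order invariance** — a seeded forest is not bit-reproducible
  under column permutation, so `rf_importance()` canonically reorders
  columns by feature name before fitting. Scores are then a pure function
  of (data, labels, n_trees, seed).

The forest uses 500 trees by default: MDI estimates stabilize with many
trees, and this selection forest is distinct from the 4-tree random-forest
*classifier* baseline, whose small size is a deliberate comparator setting.
A note on k: with ~630 development patients, the one-feature-per-ten-
patients rule of thumb suggests ~50–60 features for classical models
(hence k = 50 for the baselines), while the mapping uses k = 784 because
the CNN, not the feature count, controls capacity there.

### The spiral feature mapping

The top k = side² features are z-scored per feature with training-split
statistics and placed on a side × side grid along a center-out spiral, most
important feature at the center. The exact spiral is a convention the
package fixes and persists (any fixed, invertible center-out arrangement
satisfies the scientific requirement that importance decays from center to
edge — published descriptions of such layouts are ambiguous about
handedness, and our choice is documented rather than inferable):

* 0-based start cell `(side/2 − 1, side/2 − 1)` for even side, the exact
  center for odd side;
* first step right (col + 1), then turns counterclockwise
  (right → up → left → down) with run lengths 1, 1, 2, 2, 3, 3, …;
* cells outside the grid are skipped (the walk lives on the infinite grid,
  the layout keeps the first side² in-grid cells).

This yields a bijection rank ↔ cell that is ring-monotone: the Chebyshev
distance from the start cell never decreases with rank. Both properties
are tested for every side up to 30, and `unmap_features()` inverts any
mapping exactly.

Normalization is input standardization, not a network layer: radiomics
features span wildly different scales (voxel volumes vs. entropies), so
per-feature z-scoring is required before the values share one image plane.
`side² = k` is enforced — alternative mapping sizes (24², 32²) are
alternative selections, never padding.

### The SE-CNN

The default architecture is deliberately small, sized for cohorts of a few
hundred patients:

| stage | configuration |
|---|---|
| conv 1 | 3×3, 32 filters, same padding, ReLU |
| SE 1 | reduction r = 8 |
| pool 1 | 2×2 max |
| conv 2 | 3×3, 64 filters, same padding, ReLU |
| SE 2 | reduction r = 8 |
| pool 2 | 2×2 max |
| head | flatten → dropout 0.5 → dense 64 ReLU → dense 1 sigmoid |

All sizes are exposed in `conv_stack_config()`. The SE block squeezes each
channel to its global spatial mean, passes the C-vector through a two-layer
bottleneck gate `s = sigmoid(W2 relu(W1 z))`, and rescales each channel by
its gate. One symbol clash in common descriptions is worth stating: the
outer nonlinearity must be a (0,1) gate for channel recalibration to make
sense, so the package uses ReLU inside and the logistic sigmoid outside —
the standard SE formulation. The plain-CNN ablation is byte-identical
except that the two SE blocks are absent; forcing the SE gates to 1 with
shared weights reproduces the plain CNN's forward pass exactly, which is
one of the package's invariant tests. The 1D-CNN ablation runs the same
engine on the rank-ordered feature vector as a k×1 image (defaults:
filters 16/32, kernel 9, max pool then average pool, both of width 4).

Training is minibatch Adam (batch 50, learning rate 0.001) on the mean
binary cross-entropy with probability clipping at 1e-7; the summed form of
the loss and its per-sample gradient are exported (`bce_loss`, `bce_grad`)
and verified against finite differences. Early stopping halts after 5
consecutive epochs without validation-loss improvement and restores the
best-epoch parameters; `max_epochs` defaults to 200, far above where the
patience rule typically stops (around epoch 20–60 on the synthetic
cohort). The development cohort is split 80/20 into train/validation,
stratified by label and seeded. Every stochastic ingredient — init,
shuffling, dropout, splits — derives from explicit seeds, so training is
bit-reproducible.

The network is implemented inside the package as a small matrix-based
engine (im2col convolutions evaluated as BLAS products, with full
backpropagation through the SE gates); the whole-network analytic gradient
is checked against central finite differences in the test suite.

### Baselines and evaluation

SVM (RBF, C = 3, γ = 1), random forest (4 trees) and a two-hidden-layer
MLP (10 and 5 ReLU units, Adam) are fit on the top-50 z-scored features,
on encoded clinical covariates (gender bit, z-scored age, 8-category
subtype one-hot — all-zero when a cohort lacks subtype annotation), or on
both concatenated. The SVM contributes its signed decision value as an ROC
score: AUC is rank-based, so calibration is unnecessary; the value is
oriented so larger means mutant. The MLP mirrors the common
tolerance-based stopping rule (train-loss improvement below 1e-4 for 10
consecutive epochs).

AUC is computed from midranks (ties count one half) and is verified against
exhaustive pair counting; hard-label metrics use threshold 0.5 with
EGFR(+) as the positive class, and an undefined precision (no positive
predictions) is reported as 0 with a flag rather than NaN. The per-feature
class comparison uses the classical pooled-variance two-sample t-test
(Welch optional), signed as mean(class 1) − mean(class 0).

## The synthetic cohort generator

Real CT cohorts behind these methods are private, so the generator is a
first-class module, not a test fixture. It emulates the statistical
structure the pipeline assumes: many correlated, uninformative features
hiding a minority of discriminative ones.

* Features are unit-variance Gaussians in equicorrelated blocks
  (`x = sqrt(rho) g_block + sqrt(1-rho) e`), default block size 10 with
  rho = 0.5 — radiomics features are strongly clustered (the same metric
  across wavelet channels, size-linked shape features), and equicorrelated
  blocks are the simplest structure reproducing that redundancy.
* A seeded random subset of features (default 30 of 1000) gets a
  class-conditional mean shift of `effect_size` pooled SDs (default 1.5),
  symmetric ±d/2. Sampling the informative set from the whole catalog
  spreads it across groups and channels, so composition reporting is
  exercised.
* Labels are Bernoulli(0.5); the default cohort size is 700 with a 629/71
  development/test split, mirroring a realistic single-center study.
* Clinical covariates reproduce the usual associations: mutant patients
  skew male-enriched relative to wild-type under the defaults
  (configurable to uninformative), ages differ by ~1.6 years between
  classes, and subtypes are drawn with class-dependent frequencies.

What the generator does **not** emulate: heavy-tailed or bounded marginals
(entropies, fractions), scanner batch effects, nonlinear feature
interactions, label noise from assay error, and class imbalance beyond the
`class_balance` knob. Passing tests on this cohort therefore demonstrates
that the machinery is correct and has the claimed statistical behavior
(power, calibration, no leakage) — not that any particular clinical AUC is
attainable on real data.

## Numerical and design choices

* **Zero-variance features** are rejected at normalizer fit; **missing
  values** are rejected at load. Neither is imputed.
* **Importance ties** break alphabetically; **pooling ties** (equal values
  in a max-pool window) resolve to the first element, keeping gradients
  deterministic.
* **BCE clipping** at 1e-7 bounds the loss and gradient for saturated
  probabilities.
* **Permutation control protocol**: the control reruns the *entire*
  pipeline — selection included — under permuted labels and evaluates
  against the permuted held-out labels. With only 71 test patients a
  single null AUC has standard deviation ≈ 0.1, so the control reports the
  mean over 5 independent permutations, which estimates the chance level
  with ≈ 0.045 SD. (Training on permuted labels while keeping selection
  from the true labels is *not* a valid null: with strong planted signal,
  even the small chance correlation between a permutation and the truth
  lets the model find the real discriminant axis and score well above
  0.5.)
* **Problem sizes in the checks**: the heavyweight verifications (selection
  power and null calibration over 20 replicates; one real and five
  permuted end-to-end training runs at n = 700, p = 1000) were sized to
  make the Monte-Carlo estimates stable at a desk-scale runtime of a few
  minutes; smaller unit tests use 8×8 mappings and narrow cohorts.
* **Normalizer split**: z-score statistics are fit on the full development
  cohort (the same split selection uses), since the validation fold guides
  only early stopping; test patients contribute nothing to either.

## Known limitations

* The engine is CPU-only and sized for small images (28×28) and compact
  stacks; it is not a general deep-learning framework.
* MDI importance inherits the known bias toward high-cardinality/continuous
  features; with all-continuous radiomics features this is benign, but
  mixed-type tables would need a different selector.
* The spiral arrangement is one fixed convention; alternative arrangements
  reportedly perform similarly, and the package makes no claim of
  optimality — only of reproducibility and invertibility.
* Transfer-learning comparators (AlexNet/VGG-style), Grad-CAM heatmaps and
  image segmentation/extraction are out of scope; the package consumes
  feature tables, with extraction delegated to external tools.
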