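---
title: "N-gram texture features for medical image classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{N-gram texture features for medical image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngramimg)
```

## The model

`ngramimg` classifies grayscale images by converting them into text and
running a text-categorization pipeline on the result. The premise is that the
diagnostic signal in modalities like nodule ultrasound or retinal OCT lives in
local horizontal gray-level arrangements — short runs of intensities — which a
language model's n-grams capture directly, without committing to handcrafted
texture descriptors.

**Quantization.** Each integer gray value in [0, 255] is mapped to one of 16
letters by its 16-wide intensity bin (`A` = 0–15, ..., `P` = 240–255). Using
the raw 256-level alphabet would allow `256 + 256² + 256³` distinct tokens;
16 levels cap the vocabulary at `16 + 16² + 16³ = 4368` while retaining gray
contrast at the scale that matters for tissue texture. The mapping is defined
on integers only; non-integer pixels are rejected rather than silently
rounded, so the binning is unambiguous. The information loss is bounded: a
letter determines its gray value to within ±15 levels.

**Tokenization.** A window of length n slides left to right along every row
of the character matrix, for n = 1, 2, 3 (stride 1, no wrapping at row ends,
no vertical windows — the row is the "sentence"). An R×W matrix therefore
yields exactly `R(3W − 3)` tokens for the three orders, an identity the test
suite uses as an invariant. Orders above 3 are excluded: token-space size and
extraction cost grow geometrically with n while row-length statistics thin
out.

**Vocabulary.** The feature space is fixed by the training documents: the
union of their tokens, ordered by token length and then byte-wise
lexicographically. The ordering is a package choice — any fixed order works,
but a deterministic one makes column indices, serialized feature stores and
cross-run comparisons reproducible. Test documents are projected onto this
space; tokens never seen in training are dropped (their evidence cannot have
been used to fit anything, so they carry no representable signal).

**Weighting.** Two schemes:

* `tf`: `tf_ij = n_ij / Σ_k n_kj`, the token's share of the document's total
  token count. The denominator pools all three orders into one bag — the
  plain reading of "all words in the document". A `per_order` flag normalizes
  within each order instead, for users who prefer per-order simplexes; the
  default is pooled.
* `tf_rf`: `tf · log2(2 + (N/P) · a / max(1, c))` with `a`/`c` the counts of
  positive/negative training documents *containing* the token (presence, not
  frequency) and `P`/`N` the class sizes. The `N/P` factor is the imbalance
  compensation: with a 4:1 negative majority, a token evenly spread over both
  classes still gets factor `log2(2 + 4·1/1) > 1` pull toward the rare
  positive class. The grouping — `N/P` multiplying `a/max(1,c)` inside the
  logarithm — is implemented exactly as the formula is written.

Test documents are always weighted with training-derived `a, c, P, N`.

**Selection.** Two steps, refit inside every cross-validation training fold:

1. A two-sided Wilcoxon rank-sum test per feature column at `α = 0.05`, on
   the *weighted* values. Only significant ("valid") features survive. No
   multiple-testing correction is applied by default — the filter is
   deliberately permissive, a gatekeeper rather than an inference — but
   Benjamini–Hochberg is available via `adjust = "BH"`. The p-value uses the
   normal approximation with tie and continuity correction; with the tiny
   per-feature sample sizes of interest the accept/reject decision agrees
   with the exact permutation test ≥ 95 % of the time (tested), and the
   implementation matches `stats::wilcox.test(exact = FALSE, correct = TRUE)`
   to 1e-12 (tested). A column constant across both groups gets `p = 1`.
2. Valid features are ranked by expected cross-entropy,
   `ECE_i = p(t_i) · Σ_j p(C_j|t_i) · log2(p(C_j|t_i)/p(C_j))` — document
   frequency times the KL divergence of the token-conditional class posterior
   from the prior. Presence defines `p(t_i)`, mirroring the "sample
   frequency" reading. The top `fraction` (1.0, 0.75, 0.5 or 0.25 typically)
   is retained, with `max(1, floor(fraction · n_valid))` so a non-empty valid
   set never yields an empty model; ECE ties break by vocabulary order for
   determinism.

**Classifiers.** An RBF-kernel SVM (`C = 10`, `γ = 0.01`; the c/g pair is the
canonical RBF parameterization, so RBF is assumed) via `e1071`/libsvm, or a
small backpropagation network with hidden layers (3, 6, 3), tanh hidden
units, sigmoid output, squared-error loss, full-batch gradient descent at
learning rate 0.01 for at most 100 epochs, stopping early at MSE ≤ 1e-5, with
seeded initialization. The network is implemented in-package: its topology
has three hidden layers, which no installed single-hidden-layer fitter
expresses. Selected feature columns are standardized to training-fold
mean/sd before either classifier (flag `standardize`, on by default): the RBF
kernel is scale-sensitive, and TF values of rare versus common tokens differ
by orders of magnitude.

**Evaluation.** Stratified k-fold cross-validation (default 10; stratified so
small classes appear in every fold) with the entire feature pipeline refit
per fold. Binary tasks pool the test-fold scores into one ROC/AUC, computed
by the rank (Mann–Whitney) formulation with ties counting 1/2. Ternary tasks
train three pairwise subclassifiers per fold — each with its own vocabulary,
TF-RF weights (the pair's first class as positive) and selection, since
relevance frequency is defined only for binary problems — and predict by
majority vote; a 1-1-1 tie goes to the subclassifier with the largest
absolute decision score, a package choice where any fixed rule would do.

## The synthetic-data generator

Clinical ultrasound and OCT datasets cannot ship with the package, so
`make_dataset()` builds labeled images in which the class signal is known by
construction. Each class has background bins (pixels i.i.d. uniform over the
union of those bins' gray ranges) and a 2–3 bin horizontal motif planted
Poisson(`motif_rate`) times per row at uniform non-wrapping start columns.
The defaults — shared background bins 0–7, disjoint bright motifs
(`JKL`, `NOP`, `IMI`), one motif per row, 32×32 images — are chosen so that:

* the null token distribution is exchangeable across classes (background bins
  identical), which keeps the rank-sum filter's false-positive rate at its
  nominal α and makes the calibration property testable;
* every token touching a motif letter is class-exclusive, so the generator
  records per class exactly which tokens are "truth" (the motif's n-gram
  windows) and end-to-end recovery is checkable;
* a 32×32 image already yields ~2800 tokens, giving seconds-scale tests.

Problem sizes used by the test suite and the acceptance script — 50
images/class for the binary protocol and 20/class under 10 folds for the
ternary protocol — are desk-scale analogues of a clinical study on the order
of tens of patients per class.

What the generator does **not** emulate: speckle statistics (multiplicative,
spatially correlated noise), OCT layer anatomy, intensity gradients,
inter-device calibration drift, or any vertical structure. Passing tests
therefore demonstrate that the pipeline recovers horizontal token-level class
structure without leakage and with calibrated selection — not that it attains
any particular accuracy on clinical images.

## Preprocessing

Optional and off by default — the method is designed to tolerate coarse
preprocessing, and the feature extractor is purely intensity-based:

* `anisotropic_diffusion()`: Perona–Malik with exponential conductance,
  reflecting borders. Defaults `kappa = 30` (gray levels; edges stronger than
  ~30 levels are preserved), `dt = 0.2` (explicit-scheme stability requires
  ≤ 0.25), 10 iterations — standard practice values, all exposed. The scheme
  conserves the image mean up to rounding and never leaves the input's
  min–max range.
* `fill_white_border()`: zeroes every pixel ≥ `white_threshold` (default 250)
  that is 4-connected to the image boundary through equally bright pixels —
  the irregular white frame of some scan exports. Flood-fill from the
  boundary is an interpretation of "identify the edges and fill the
  deselected area with black"; interior bright structures are untouched by
  construction.
* `rotate_longest_diameter_horizontal()`: orients a region's maximum Feret
  diameter (farthest boundary-point pair, found on the convex hull)
  horizontally, removing nodule-angle variation. Bilinear interpolation for
  the image, nearest-neighbor for the mask (so it stays binary); the canvas
  expands with zero fill. On rasterized masks the post-rotation residual is
  below 2°. Region segmentation itself is out of scope — masks are supplied.

## Numerical and degenerate-input choices

* Rank-sum on a constant column: `p = 1`, never an error — constant features
  are common in sparse token matrices.
* Zero-token documents: TF row of zeros (no division by zero), scored like
  any other document.
* Standardization of a zero-variance selected column: sd treated as 1.
* All randomness flows from one top-level seed, split deterministically
  per component (fold assignment, per-fold network seeds, per-image
  generator seeds); RNG state of the caller is saved and restored, and
  identical seeds give byte-identical reports (tested).
* Fractional retention floors at one feature; an empty valid set yields an
  empty selection with a warning at the selection layer and an error inside
  a CV fold, where a model could not be fit.

## Known limitations

* Horizontal-only tokens: rotationally variant by design; the rotation
  preprocessor exists precisely to normalize orientation before extraction.
* The rank-sum filter tests marginal location shifts only; feature
  interactions are invisible to it.
* TF-RF (and hence the ternary subclassifiers' weighting) is inherently
  binary; multiclass problems use it pairwise, not globally.
* The backprop network is a minimal reference implementation tuned for
  determinism and the configured 3-6-3 topology, not a general-purpose deep
  learning tool.
* File I/O covers PNG, TIFF and JPEG; BMP is not read by the available
  decoders.
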