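---
title: "Virtual hexagonal trellis features for white blood cell classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual hexagonal trellis features for white blood cell classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhtrellis)
```

## The problem

A manual leukocyte differential classifies white blood cells on a stained
smear into eosinophils, lymphocytes, monocytes and neutrophils, chiefly by
nucleus morphology. Automating this on microscope crops is complicated by
dark irregular backgrounds, low cytoplasm contrast, and uneven illumination.
`vhtrellis` implements a compact pipeline for this task: hand-crafted
gradient texture features derived from a *virtual hexagonal trellis* (VHT),
optionally fused with deep features, classified by SVM/KNN variants.

## The trellis kernels

Within a 3×3 neighbourhood (`f1..f9` row-major, centre `fc`) four virtual
elements are inserted halfway between the centre and each corner, each
carrying the mean of the two intensities (`h1 = (f1+fc)/2`, ...). These ten
sites form a hexagonal trellis over the square lattice. The directional
difference along x, `(f6+h2+h4) − (f4+h1+h3)`, expands after substitution to
`½(2f6 + f3 + f9 − 2f4 − f1 − f7)`; the centre pixel cancels exactly. The
package performs this expansion in exact rational arithmetic
(`expand_directional_difference()`), so the cancellation is symbolic, not a
floating-point accident, and maps the result onto a 3×3 kernel
(`kernel_from_expression()`).

```{r kernels}
expand_directional_difference("x")
kernel_matrices(canonical_kernels())$x
```

Two derivational facts are worth recording, because the design resolves
them deliberately:

* The y-direction expansion `½(f7 + f9 − f1 − f3)` and the matrix the
  canonical set uses for y, `½[1 2 1; 0 0 0; −1 −2 −1]` (a Sobel-style
  operator), are *not* the same object: the expansion has an empty centre
  column and opposite sign. The symbolic module reproduces the expansion
  faithfully; the canonical kernel set (`canonical_kernels()`) adopts the
  matrix form for feature extraction, keeping the two roles separate rather
  than silently "correcting" either.
* Summing the integer bracket matrices of the x and y kernels gives
  `[0 2 2; −2 0 2; −2 −2 0]`; its GCD factor 2 (`gcd_factor()`) is pulled
  out to store the 45° diagonal kernel unit-scaled. Gradient features are
  normalized downstream, so the overall diagonal scale (2 vs ½) is
  immaterial; the factored scale is kept as metadata (`mxy_scale`), not
  baked into the kernel. The 135° operator is the column mirror of the 45°
  one — mirroring a diagonal edge operator yields the orthogonal diagonal
  operator and preserves the zero-sum property.

Response maps are computed as a sliding dot product (no kernel flip) with
reflect-101 border padding. The dot-product orientation is forced by the
symbolic contract: evaluating the expansion on a neighbourhood must equal
applying the derived kernel to that neighbourhood, which the test suite
checks exhaustively over random neighbourhoods. With the fixed layout
(`f1..f3` on top, rows increasing downward), `k45` responds to intensity
ramps rising toward the upper right (`c − r`) and is exactly zero on the
orthogonal `r + c` ramp.

## The feature descriptor

`vht_extract()` pools five statistics per response map over a 4×4 grid of
cells: mean, mean absolute value, energy (mean square), standard deviation,
and the Pearson correlation between the cell's response and luminance
values. With 4 maps × 16 cells × 5 statistics this yields a fixed-length
**320** descriptor at the standard 200×200 side. Fixing the length is a
deliberate contract: every fusion experiment downstream indexes VHT
features positionally, and a descriptor whose length varied with image
content could not be fused or compared across images. Grid and statistics
are configurable for other geometries; the length then scales as
`4·g²·5`.

Conventions chosen where more than one definition was defensible:

* Grayscale conversion uses Rec. 601 luminance weights (0.299, 0.587,
  0.114).
* The correlation of a zero-variance cell is defined as 0, keeping vectors
  finite on flat regions.
* Under intensity scaling `a > 0`, mean/|mean|/SD features scale by `a`,
  energy by `a²`, and correlations are invariant — a property the test
  suite asserts at `a = 2` and `a = 0.5`. Classifier-side standardization
  removes the remaining scale dependence.

## The deep backend and its surrogate

The deep feature source is a *contract* (`feature_backend()`): any
deterministic image → fixed-length-vector transform, with a default output
width of 4096 (the fully-connected width typical of AlexNet-family CNNs).
The shipped implementation, `surrogate_backend()`, pools 8×8 block means
and SDs of the luminance image and of the four gradient response maps (640
raw statistics) and projects them through a fixed seeded Gaussian random
projection. This is a genuine multiscale image descriptor — deterministic,
fast, and discriminative on the synthetic classes — and it exercises the
selection and fusion stages with realistic dimensionality. Training a CNN,
or re-using trained weights, is out of scope; users with a trained network
plug it in behind the same contract.

## Ant colony feature selection

`aco_select()` chooses exactly `k` of the deep features. Each of `ants`
ants per iteration samples `k` distinct indices with probability
∝ τᵢ^α · ηᵢ^β, where η is a Fisher discriminant ratio (between-class
variance of class means over pooled within-class variance) and τ the
pheromone, initialized at 1 and clamped to [0.01, 10]. Fitness is the mean
stratified 3-fold cross-validated accuracy of a linear SVM on the subset;
pheromone evaporates by `1 − ρ` per iteration and the iteration-best subset
deposits `ρ ×` its fitness. Defaults (20 ants, 30 iterations, α = β = 1,
ρ = 0.2) follow common ACO-for-feature-selection practice; the subset size
is exact rather than emergent because every fusion experiment uses an exact
count. On a planted-signal benchmark (200 samples × 100 features, 5
informative features at ±2 SD) the selector recovers at least 4 of the 5
planted features, which the acceptance tests verify.

## Fusion, classifiers, and metrics

Serial fusion is plain ordered concatenation (`fuse()`), so fused lengths
add exactly (100+100→200, ..., 400+320→720, 750+320→1070). The VHT side is
truncated positionally (first `k` features in layout order) when a smaller
VHT budget is requested, since the descriptor has no selection stage of its
own.

Nine classifier variants are exposed (`classifier_variants()`). SVM
variants standardize features with training statistics and use one-vs-one
decomposition with box constraint 1: linear; polynomial degree 2 and 3; and
Gaussian RBF at kernel scale `√d/4`, `√d`, `4√d` (fine/medium/coarse) for
`d` features — the documented convention of the toolbox family these
variant names come from. KNN variants are fine (k=1) and coarse (k=100)
Euclidean and cosine (k=10); per-class scores are the vote fractions among
the k nearest neighbours.

`evaluate_model()` reports the confusion matrix; per-class one-vs-rest
accuracy, sensitivity, specificity, PPV, NPV, F-measure and G-measure
(every 0/0 defined as 0; a class absent from both truth and prediction is
reported as `NA` and excluded from macro averages); macro averages; the
overall accuracy `trace/total` with `error = 1 − accuracy`; and per-class
AUCs via the tie-corrected rank form of trapezoidal ROC integration
(cross-checked against an independent ROC implementation in the tests).
Overall (trace/total) accuracy and the macro average of per-class
one-vs-rest accuracies are different quantities; the report keeps both,
with `Acc` in the grid table referring to the former.

## The synthetic generator

`render_cell()` emulates the features of stained smear crops that drive
this pipeline: a near-black background (base level 8–30 of 255) with dark
blotches; a multiplicative linear illumination gradient (default relative
strength 0.35) in a random direction; a pink, low-contrast cytoplasm disc
of radius 55–75 px with radial shading; a purple nucleus whose shape is
class-specific — lymphocyte: one round nucleus at 0.82 of the cell radius
(≥ 60 % of the cell area); monocyte: a 0.75-radius disc with a 0.50-radius
bite (kidney form); eosinophil: two 0.40-radius lobes plus dense granular
speckle in the cytoplasm; neutrophil: 3–5 separated 0.22–0.26-radius lobes
on a ring — plus Gaussian sensor noise (SD 3) and sparse impulse noise
(density 0.002). These defaults were chosen once so that the classes
differ in gradient texture (the signal the VHT descriptor measures) at
difficulty comparable to visual inspection of real smears, and are all
overridable in `smear_config()`.

What the generator does **not** emulate: staining variability between
laboratories, red blood cells and platelets in the frame, focus blur,
chromatin texture inside the nucleus, and touching or clipped cells.
Passing tests on synthetic data therefore demonstrate that the pipeline's
machinery is correct and discriminates morphology as designed — not that
the reported accuracies transfer to any real clinical dataset. Runs on real
data use the `directory` source of `pipeline_config()`.

## Numerical and protocol choices

* Augmentation ops cycle in a fixed order (right 90° rotation, horizontal
  flip, vertical flip, salt-and-pepper at density 0.02, half salt half
  pepper, seeded); balancing never deletes original rows.
* Autocrop keeps the bounding box of pixels with max channel ≥ 20/255 —
  an automated stand-in for the manual cropping such datasets usually get.
* Train/test protocol: stratified 75/25 split, seeded. ACO selection runs
  on the training split only; selecting on all data would leak the test
  set into the selection step.
* Every stage takes an explicit seed and restores the caller's RNG state,
  so identical configurations give byte-identical artifacts; the
  acceptance tests compare reports of two runs by checksum.
* Problem sizes in the test suite: the end-to-end acceptance run uses 150
  synthetic images per class with a (100 deep + 100 VHT) fusion and the
  default ACO budget; unit tests use 64-pixel thumbnails and reduced
  colony budgets, which keep the full suite within ordinary desktop
  runtimes while exercising every contract at full fidelity.

## Known limitations

* The surrogate backend is linear in its pooled statistics; it is a stand-in
  for exercising selection and fusion, not a claim about CNN-grade feature
  quality.
* The VHT descriptor is global-grid based; it assumes the cell is roughly
  centred and fills much of the frame, as in per-cell crops. Whole-slide
  images need detection/cropping first.
* KNN variants compute dense distance matrices; they are fine at
  thousands of samples but not designed for much larger datasets.
* The coarse KNN default (k = 100) exceeds small training sets; k is
  capped at the training size in that regime.
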