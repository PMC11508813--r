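---
title: "Methods: models, conventions and design choices in whealmeter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in whealmeter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A skin prick test is read from the wheal that forms at each prick site.
The clinical standard measures two ruler diameters — the largest diameter
LD and the perpendicular diameter PD — and summarizes the reaction either
as a circle of diameter (LD + PD)/2 (area MA1) or as an ellipse with axes
LD and PD (area MA2). Both are geometric idealizations; strongly positive
reactions form pseudopods whose area neither captures. `whealmeter`
measures area directly: segment the wheal pixels in a photograph, count
them, and scale by a 3 x 3 cm reference tag (RT) photographed in the same
frame:

    area_cm2 = 9 * wheal_pixels / rt_pixels.

Because this estimator depends only on the pixel count, it is invariant
to the wheal's contour. The package's comparison machinery exists to
quantify exactly that contrast: on regular shapes all estimators agree;
on irregular shapes the diameter-based ones drift.

The calibration assumes square pixels and a camera roughly parallel to
the skin (the capture protocol it emulates makes the same assumption);
perspective rectification of the tag is an explicit non-goal.

# Label masks

Masks use three classes with a fixed file encoding: wheal magenta
(255, 0, 255), reference tag black (0, 0, 0), background red (255, 0, 0).
Decoding is strict — any off-palette pixel is an error naming the first
offending coordinate — and encode/decode round-trips bit-exactly, which
is why masks are written as lossless PNG. In rendered scenes the tag is
drawn chroma green; the black is a property of the annotation code, not
of the photographed tag.

# Synthetic data

The generators state the world the tests run in:

- **Shapes.** Circles and ellipses carry their analytic area pi*a*b.
  Pseudopods are a base ellipse plus 3–8 Gaussian radial lobes,
  r(theta) = r_ellipse(theta) + sum A_i exp(-(theta - theta_i)^2 / (2 sigma_i^2)),
  with amplitudes drawn as 15–45 % of the minor semi-axis and angular
  widths of 10–35 degrees. Amplitudes are strictly positive, so r(theta) > 0
  everywhere and every pseudopod is connected by construction; a defensive
  connectivity check remains but cannot trigger. Pseudopods have no
  closed-form area — in the irregular-shape study the pixel-proportion
  estimate is the reference, mirroring how the study design argues for it.
- **Rasterization rule.** A pixel belongs to a shape iff its center lies
  strictly inside the analytic boundary. This is the simplest rule with a
  closed-form oracle; the tests assert the implied O(1/r) area
  convergence (< 1 % relative error at radii >= 30 px).
- **Scenes.** Flat skin-tone background (default RGB 224/172/138), a
  slightly redder wheal fill, a chroma-green tag, and Gaussian intensity
  noise (default sigma 0.02 on the 0–1 scale). The emulated capture
  protocol deliberately avoided standardization, so tone, noise and scale
  are parameters, not constants. The default scale of 100/3 px/cm puts
  the tag at about 100 x 100 px on the standard 640 x 480 canvas.
- **Placement.** Shape-group files place the tag at a fixed corner and
  shapes by rejection sampling with a 3 px clearance between
  circumscribed circles, so 8-connected components never merge. Explicit
  scenes check true pixel-set overlap and name the offending shape.
- **Augmentation.** The mirroring chain — original, horizontal mirror,
  then vertical (a 180-degree rotation), then horizontal again (the pure
  vertical mirror) — quadruples a dataset and preserves class histograms.
- **Determinism.** Every generator is bit-reproducible given its
  parameters and seed; seeds are scoped so generation does not disturb
  the caller's RNG stream.

What a green test on this world establishes: the measurement chain (from
pixels to areas, diameters and agreement statistics) is correct to known
tolerances. What it does not establish: segmentation performance on real
photographs — real skin texture, lighting, hair, moles, lens distortion
and annotation noise are all absent. The published clinical metrics
(85.88 % segmentation accuracy, 70.29 % sensitivity, 98.94 % specificity,
DSC 80.85 %, IoU 69.65 %, rho = 0.88 against assisted segmentation) were
measured on a private 30-image validation set with the original trained
weights, and are therefore documentation context here, not a
reproducible target.

# Segmentation network

The model is a classic fully convolutional network: a VGG-16 encoder
(five blocks of 2/2/3/3/3 3x3 convolutions, ReLU, each followed by 2x2
max-pooling), a two-layer convolutional head (7x7 then 1x1, 4096 filters
each at full width), a 1x1 class-score convolution, and an FCN-8s skip
decoder: 2x upsampling summed with a 1x1-adjusted pool4 score, 2x again
with the pool3 score, then 8x upsampling into a per-pixel softmax over
the three mask classes. Input dimensions must be divisible by 32.

Design points the architecture description leaves open, and the choices
made:

- **Upsampling operator:** learnable transposed convolutions (kernel 2s,
  stride s, pad s/2) initialized to bilinear interpolation — the standard
  FCN-8s choice.
- **Skip adjustments:** the 1x1 pool3/pool4 score convolutions are
  zero-initialized so early training follows the skip-free path; a
  standard stabilization.
- **Initialization:** He-normal, fixed seed; no pretrained VGG weights
  are assumed (transfer learning is never mentioned in the source
  protocol).
- **Loss:** unweighted cross-entropy. No class weighting is specified
  anywhere; the observed high-specificity / moderate-sensitivity profile
  of the original model is consistent with unweighted loss on imbalanced
  classes.
- **Head padding:** "same" padding for the 7x7 head convolution.
- **Ties at argmax:** resolved toward background, so an uninformative
  uniform probability map predicts no wheals rather than spurious ones.
- **Validation:** `validation_fraction` defaults to 0; the evaluation
  protocol supplies its validation data externally.

Training defaults equal the published recipe (400 epochs, batch 32,
Adam, learning rate 1e-4, cross-entropy); the batch size clips to the
dataset. The engine is written in RcppArmadillo (im2col + GEMM
convolutions) because no deep-learning framework is available in the
target R stack; it is exact but CPU-bound, so the **desk-scale profile**
— `width_multiplier = 1/16`, 64 x 64 inputs — is the tested
configuration. Full-width 640 x 480 training is supported but
GPU-inappropriate by construction and flagged as such. The training
smoke test uses 64 x 64 close-up scenes at 6 px/cm with one large wheal
each and learning rate 1e-3: small enough to run in about a minute,
large enough for the model to memorize its 8 training scenes.

# Geometric measurement

- **Clustering:** 8-connected components (the permissive standard; no
  connectivity is specified by the protocol), `min_size = 10` px to
  suppress single-pixel speckle, clusters numbered 1..n in row-major
  centroid order so overlay numbering is stable across runs.
- **Calibration:** the largest 8-connected tag component is the tag
  (smaller rt-class fragments are treated as misclassifications);
  `cm2_per_pixel = 9 / rt_pixel_count`, `cm_per_pixel` its square root.
- **Diameters:** chords through the pixel centroid, not maximal pairwise
  distances — the computational protocol explicitly relies only on the
  geometric center. For each angle (default sweep step 1 degree,
  smallest-angle tie-break) the full line through the centroid is marched
  at 0.25 px steps with nearest-pixel membership; the chord is the span
  between the extreme in-region pixel centers plus 0.5 px at each end,
  which is unbiased for center-sampled rasterization. The perpendicular
  chord is evaluated at the LD angle + 90 degrees exactly (off the sweep
  grid) and clamped to LD to preserve the LD >= PD invariant against
  sub-pixel slivers. If the centroid falls outside the region (a strongly
  non-convex shape), the chord degrades to the total in-region extent
  along the line and a warning is raised.
- **MA1/MA2:** direct evaluation of the circle and ellipse formulas;
  MA1 >= MA2 always, with equality iff LD = PD (AM–GM).

An early implementation measured chords from 4-connected boundary pixels
inside a half-pixel band; on diagonal lines the extreme digital-line
pixel need not be a boundary pixel, which silently truncated chords. The
marching formulation replaced it and is cross-checked in the tests
against a dense 0.1-degree all-pixel-band oracle.

# Evaluation

Detection matching is greedy one-to-one by descending pixel-overlap IoU
with an any-overlap threshold; leftovers are type I (spurious) and type
II (missed) errors, and detection accuracy is
100 * correct / (expected + type I). The matching rule is not specified
by the source protocol; greedy-IoU reproduces its counting behavior and
is verified against exhaustive assignment on small instances.

Per-wheal confusion metrics are computed in a local window — the
bounding box of the union of the matched clusters, dilated by `pad_px`
(default 5) — because "a cluster of pixels around the wheal" leaves the
window open. The window only affects TN-dependent metrics (accuracy,
specificity); sensitivity, DSC and IoU are window-invariant, and
`pad_px` is recorded in every report. Per-wheal metrics are
macro-averaged (unweighted across wheals).

# Method agreement

- **Bland–Altman:** bias = mean difference, limits of agreement
  bias ± 1.96 sd (the multiplier is the standard normal quantile; none
  is printed in the source). Proportional bias is the Pearson
  correlation of differences against pair means with a two-sided t test
  — the standard operationalization of "differences concentrate around
  a bias". Zero-variance differences set a `constant_diff` flag and
  report the undefined correlation as 0.
- **Wilcoxon:** zero differences are dropped (the original convention —
  relevant because ruler-discretized MA1/MA2 produce ties); exact null
  distribution for n <= 25 without ties, tie-corrected normal
  approximation with continuity correction otherwise. The exact path is
  validated against full 2^n sign enumeration.
- **ECDF superposition:** each non-reference sample is shifted by its
  Bland–Altman bias and the Kolmogorov-style max vertical distance to
  the reference ECDF is reported before and after. Exact superposition
  for a constant offset holds under exact arithmetic; the tests use
  dyadic sample values because a non-representable offset can move a
  value across a tie and leave an O(1/n) residual distance.
- **Cumulative-mean convergence:** 15 shuffles by default; per-shuffle
  running means, their average, and the sd/sqrt(k) standard-error decay.
- **Deviation studies:** absolute percentage deviations (signs are
  discarded; the summaries are nonnegative), reference = analytic area
  for regular shapes, pixel-proportion area for irregular ones. No
  equivalence margin is invented: statistically significant Wilcoxon
  differences and usable agreement coexist by design.

# Numerical conventions

Coordinates are 0-based (row, col) with pixel centers at integer
positions; cluster pixel tables are 1-based R matrix indices, centroids
0-based reals. Probability maps are softmax-normalized per pixel to
within 1e-5. Report JSON serializes floats at full precision
(`digits = NA`); the overlay legend rounds to 2 decimals for display
only. All randomness flows through explicit seeds.

# Known limitations

- No perspective/homography correction of the tag; tilted captures bias
  the calibration quadratically in the tilt.
- The synthetic scenes are flat-toned; the network results on them say
  nothing about real-skin robustness (see above).
- Chord measurements are +0.5 px-per-end conventions on a digital
  region; below ~30 px of diameter the discretization error dominates.
- Full-resolution training (640 x 480, width 1) is supported but
  impractical on CPU; only the desk-scale profile is exercised by the
  test suite.
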