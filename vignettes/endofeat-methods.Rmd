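---
title: "Hand-crafted visual features of endoscopic bleeding: methods and design"
author: "endofeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hand-crafted visual features of endoscopic bleeding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endofeat)
```

## The problem

Detecting blood in gastrointestinal endoscopy video is a binary image
classification task with strong colour structure: fresh blood occupies a
narrow band of reds in which the red channel dominates green and blue while
green and blue stay close to each other. Deep networks learn this eventually,
but with the modest datasets typical of endoscopy it helps to hand the
network explicit, interpretable clues. `endofeat` computes nine such clues —
high-level visual features of bleeding — as *feature activation maps*:
single-channel images, the same size as the frame, whose intensity encodes
the local strength of one feature. The maps can be appended to the RGB
channels to form a 12-channel CNN input, and they double as a standalone,
network-free bleeding localizer.

The package covers everything around that idea that can be built and tested
without a clinical dataset: the descriptors themselves, automatic
region-of-interest (ROI) masking, channel fusion and first-layer kernel
adaptation, feature-map localization with bounding-box IoU scoring, the full
set of ROC-based evaluation metrics with operating points, dataset balancing
and examination-grouped folds, an augmentation battery, and a seeded
synthetic frame generator that stands in for real endoscopy stills in every
test.

## The nine descriptors

All per-pixel arithmetic happens in floating point after byte extraction,
with the shared normalization operator
`normalizeRange(x, lo, hi) = clip((x - lo)/(hi - lo), 0, 1)` (clipping
before or after the linear map is equivalent).

**F1 — blood colour region.** The reference descriptor, and the only one
whose parameters are fully pinned down. With `g` and `b` floored at 1:

    c1 = norm( min(r/b, r/g) / 255, 0.003, 0.01 )
    c2 = 1 - |b - g| / 255
    F1 = norm( c1 * c2^5, 0.02, 1.1 ),   cleared where r < 30 or ROI = 0

`c1` measures the excess of red over both other channels, `c2` the
green/blue proximity typical of blood; the fifth power makes `c2` a sharp
gate. A note on reading the ratio coefficient: we interpret the published
`min(rb^-1, rg^-1)/255` as element-wise division (`r/b`, `r/g`), the reading
consistent with the accompanying description of `c1` as "the minimum of the
r/b and r/g ratios". The alternative subtract-one reading
(`(min(r/b, r/g) - 1)/255`) would shift the activation window; under the
adopted reading a neutral gray pixel retains a small residual activation
(about 0.10) rather than exactly zero, and everything downstream (region
thresholds in F3/F6/F7, the localizer) is parameterized with that in mind.

**F2/F5 — smooth surface.** Large pools of blood cover the mucosa with a
compact, smooth surface. F2 multiplies F1 by a smoothness score
`1 - norm(local std of gray intensity, 2, 20)` computed in an 11 px box
window (intensities on the 0–255 scale). F5 applies the same gate to F4.

**F3/F6 — clear region boundary.** Blood regions often show a sharp edge
against normal tissue. Connected regions of F1 activation above 0.5 are
extracted; a region is painted 1 over its whole interior when at least 20%
of its contour pixels lie on a Sobel gradient magnitude above 100. Painting
the interior (rather than the contour band alone) makes the map mark *where
the clearly-bounded blood is*, which is what the localizer needs. F6 runs
the same test on F4 regions.

**F4 — red colour region.** The F1 pipeline with a relaxed ratio window
(`c1` normalized over [0.0015, 0.01]) and a weaker proximity exponent
(`c2^2`), accepting washed-out or atypical shades of red that the strict
blood window rejects.

**F7 — dispersed blood.** Small amounts of blood appear as spots, streaks
and spray. The per-pixel blood-colour test (F1 activation above 0.5, before
any area reasoning) is kept only on connected components no larger than 1%
of the ROI area; large coherent pools are deliberately ignored, as they are
F1/F2's territory.

**F8 — red colour domination.** An image-level feature: the fraction *f* of
ROI pixels passing a wide red test (`r > g + 20` and `r > b + 20`),
excluding unclear pixels — near-saturated highlights (`min(r,g,b) > 230`)
and near-darkness (`max(r,g,b) < 30`). The output is the constant map
`norm(f, 0.25, 0.75)`, calibrated so the 0.5 output level corresponds
exactly to red covering half the image.

**F9 — blur.** High colour variance with few edges indicates a blurred
frame: `norm(v, 100, 2000) * (1 - norm(e, 0.01, 0.10))` with *v* the global
gray variance and *e* the fraction of ROI pixels whose Sobel magnitude
exceeds 200. F8 and F9 are emitted as constant-valued maps inside the ROI so
the 12-channel stacking contract stays uniform.

Only F1's numeric parameters are published; the F2–F9 values above are this
package's declared defaults, chosen once so that the generator's blood and
mucosa fixtures separate cleanly, and exposed for override through
`descriptorDefaults()` and the JSON run config (`readRunConfig()`).

## ROI detection

The published pipeline treats ROI detection as a fast preprocessing stage
but does not describe its algorithm, so `detectRoi()` is a declared
reconstruction: candidate foreground is `max(r,g,b) > 12` (analog borders
are near but not exactly black); the largest connected component is kept,
which drops bright overlay text in the border; closing with a 15 px disc
and hole filling absorb specular gaps; a final 3 px erosion keeps
descriptors off the dark rim. The final erosion means re-applying the
detector to a masked frame shaves another ring, so the mask is stable
rather than strictly idempotent (it never grows, and the re-applied mask
agrees with the original at IoU > 0.95).

## Fusion with a CNN

`stackChannels()` scales RGB by 1/255 so all twelve channels share the
[0, 1] range (the numeric range fed to the network being otherwise
unconstrained), and `toModelInput()` resizes each channel independently to
224 × 224 with separable Catmull–Rom cubic interpolation, clipping the
cubic overshoot back into [0, 1]. Features are computed at native frame
resolution and resized afterwards, preserving their full spatial support.

Adapting an RGB network requires only its first convolution layer to accept
12 input channels. `expandInputKernels()` preserves the three original
kernel slices bit-exactly and initializes the nine new slices either to
zero — the default, which is *function-preserving*: with zeroed feature
channels the expanded network reproduces the original output to floating
point round-off — or to the mean of the RGB slices, a transfer-learning
start that gives the feature channels a non-trivial initial gradient. How
the extra slices "should" be initialized is genuinely open; both modes are
offered and the identity property of the zero mode is tested. Ensembling is
plain output averaging (`ensembleScores()`).

## Localization and its scoring

`fmapLocalize()` averages channels F1–F7 (F8/F9 carry no spatial
information) and applies the postprocessing operator *p*
(`postprocessP()`): min-max normalization to [0, 1] followed by a 0.5
threshold. A constant map yields all zeros — no pixel is distinguished, and
declaring the whole frame a detection would be worse than declaring
nothing. `combineMaps()` fuses the Fmap with an externally supplied
saliency map (Grad-CAM and relatives are consumed as grayscale rasters,
never reimplemented) by averaging the two min-max-normalized maps before
*p*.

Scoring uses bounding boxes, not pixel masks, because saliency maps are
typically low-resolution: `maskToBbox()` takes the tight box over *all*
above-threshold pixels (a single enclosing box, with no small-component
filtering), in 0-based half-open coordinates so that box area is an exact
integer count. `bboxIoU()` is the usual intersection-over-union;
`evaluateLocalization()` averages per-image IoUs, scoring an empty
prediction against a non-empty reference as 0 and empty-vs-empty as 1
(cases the bounding-box formulation leaves undefined).

## Metrics

`fullReport()` computes ROC AUC (rank-based, tying to the probabilistic
interpretation `P(pos > neg) + 0.5 P(equal)`); F1/F2, sensitivity,
specificity, precision and accuracy at the 0.5 threshold with ties counted
as positive; and six operating points. Attainment is conservative and
non-interpolating: `sens@fpr` reports sensitivity at the smallest threshold
whose achieved FPR does not exceed the request, `spec@sens` the specificity
at the largest threshold whose sensitivity reaches it. When there are fewer
negatives than `1/fpr` the requested rate cannot be resolved and the result
carries a `degenerateResolution` flag. One naming wrinkle is resolved here:
the metric table's last three rows are labelled like sensitivities in some
renderings but defined as specificities at forced sensitivity; the
specificity reading is implemented (`spec@0.95`, `spec@0.99`,
`spec@0.999`).

## Data preparation

Positive (blood) samples smaller than 100 images are balanced by cyclic
duplication of their image list up to 100; negatives are never balanced and
no image is ever removed. Cross-validation folds partition *examinations*,
never images, so all frames of one exam share a fold. The augmentation
battery (rotation, flips, skew, perspective, blur, noise, hue and
saturation distortion, PCA colour shift) draws each magnitude uniformly
from a configured closed range per application and is bit-deterministic
under a seed; the default ranges (±15° rotation, ±10° hue, ×[0.8, 1.2]
saturation, …) are declared defaults, as only the transform set itself is
fixed by the method.

## The synthetic generator

`generateFrame()` renders what the descriptors assume about analog-capture
endoscopy: a black border with bright overlay-text blocks, a bright
circular (or rounded-rectangular) field of view, mucosa at (185, 125, 105)
with low-frequency texture (white noise of std 8 smoothed with a 3 px
Gaussian, shared across channels so local colour ratios stay near the
mucosa base), blood ellipses at (150, 22, 28) — ratios r/g ≈ 6.8,
r/b ≈ 5.4, |g − b| = 6, comfortably inside F1's high-activation regime —
plus optional washed-red distractors, specular highlights, bubble rings and
frame blur. Exact blood and field-of-view masks come back with every frame.

What the generator does *not* emulate matters for interpreting green tests:
real mucosa has vascular texture, specular sheen and depth shading; real
blood mixes with fluids and varies in hue; interlacing artifacts are absent
by the still-frame input contract. Passing tests therefore demonstrate that
the algorithms implement their definitions and separate the colour regimes
they were designed around — not that clinical-level accuracy (the 0.963
ensemble ROC AUC or the 0.517 Fmap IoU reported on real data) transfers.
Those numbers require the private clinical dataset and trained ensembles
and are out of scope by design.

One internal tension is worth recording: under the adopted element-wise
ratio reading of F1, any pixel with r ≥ max(g, b) — including default
mucosa — retains a small positive activation, so the generator's
"mucosa ≈ 0" ideal holds only as separability (mucosa stays far below the
0.5 region threshold; blood sits far above it). The test suite asserts
exactly that, and the localizer's normalize-then-threshold postprocessing
makes the residual harmless.

## Problem sizes and numerical choices

The test suite and the acceptance script run the 50-frame suites at
360 × 288 (half PAL) and ROI recovery at full 720 × 576; these sizes are
the package's own choice of test conditions, with the generator default
remaining 720 × 576. Tolerances: the vectorized F1 must match a per-pixel
scalar trace to 1e−9; box IoU must match pixel-set enumeration to 1e−12;
rank-based AUC must match the O(n²) pairwise oracle to 1e−12; the
zero-init kernel expansion must reproduce the baseline forward pass to
1e−6. Degenerate inputs are decided, not left to chance: constant maps
binarize to zero, empty predictions score 0 against non-empty references,
`fBeta(0, 0) = 0`, and a frame with no bright pixel raises an empty-ROI
error rather than returning an empty mask.

## Known limitations

* F2–F9 parameters are defaults tuned on synthetic separability, not on
  clinical data; real deployments should revisit them via the JSON config.
* The ROI detector is a reconstruction; exotic vendor overlays that touch
  the field of view could survive the largest-component rule.
* The localizer inherits F1's colour model: dark clotted blood below the
  red floor (r < 30) is invisible to it by construction.
* `augmentImage()`'s geometric warps use bilinear resampling with replicate
  borders; heavy perspective jitter near corners stretches border pixels.
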