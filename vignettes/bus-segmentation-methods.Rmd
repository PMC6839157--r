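---
title: "Methods: encoder-decoder CNN segmentation of breast ultrasound lesions"
author: "BUSseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoder-decoder CNN segmentation of breast ultrasound lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BUSseg)
```

## The problem

Breast ultrasound (BUS) images are grayscale, low-contrast, and corrupted
by multiplicative speckle. Radiologists read lesion *margins* as a key
malignancy cue: benign lesions tend to show a smooth, roughly elliptical
outline, while malignant lesions show irregular, spiculated, angulated
contours. BUSseg frames lesion delineation as two-class semantic
segmentation — every pixel is labelled 0 (background) or 1 (lesion) — and
asks whether convolutional encoder–decoder networks, and in particular
DAG variants with skip aggregation, can recover those irregular margins.

## The three architectures

All three networks share the same main path. The encoder applies three
sub-sampling modules, each `Conv(3x3)-BatchNorm-ReLU` twice followed by a
2x2 max-pool of stride 2, so a 160-pixel input reaches a 20x20
bottleneck. Two further conv blocks sit at the bottleneck. The decoder
mirrors this with three up-sampling modules (`Deconv(4x4, stride 2)` each
exactly doubling the resolution, then `Conv-BN-ReLU`), a dropout layer
(ratio 0.5) after the first, a final size-preserving max-pool, a 1x1
convolution producing the two class maps, batchnorm, ReLU, softmax, and
a pixel-classification sink. Every convolution uses stride 1 and
size-preserving padding with 64 feature maps by default; weights start
from N(0, 0.01^2) with zero biases.

- **CNN1** is the plain series chain: one path from input to output,
  52 processing layers.
- **CNN2** adds one skip path: the output of the first module's second
  ReLU (full resolution) is brought down to the resolution after the
  first deconvolution by two `MaxPool -> Conv-BN-ReLU` steps and
  depth-concatenated into the decoder (9 added layers, 61 total).
- **CNN3** taps all three encoder modules after their second
  convolution's ReLU and carries each to full resolution — a
  `Deconv -> Conv-BN-ReLU` step per 2x of up-sampling, and a
  `Conv-BN-ReLU` adapter for the branch already at native scale — before
  a single depth concatenation feeding the final 1x1 convolution
  (16 added layers, 68 total).

Two compositional details were genuinely open and are our design
choices. First, aggregation: we concatenate along the channel dimension
(the following convolution absorbs the widened input), since
concatenation preserves both information streams and is trivially
swappable for addition behind `buildNetwork()`. Second, the skip-branch
internals: only the tap points and the resampling operators are fixed by
the architecture description; our branches pair every resampling step
with a `Conv-BN-ReLU` block, which mirrors the one fully specified
branch (CNN2's) and makes the three variants count 52, 61 and 68 layers
— consistent with each other under a single uniform rule. A related
reading note: the series description enumerates twelve convolutions
while the accompanying prose says eleven; we follow the enumeration,
which is also what the printed layer totals require.

The final max-pool uses stride 1 with size-preserving padding: a
stride-2 pool at that position would halve the output and contradict the
requirement that the predictive map match the input size. This is a
documented deviation from the blanket "stride 2" wording for pooling
layers.

```{r counts}
vapply(c("CNN1", "CNN2", "CNN3"),
       function(v) countLayers(buildNetwork(v, 160L)), 0L)
```

## Training

Optimization is stochastic gradient descent with momentum,

$$\theta_{l+1} = \theta_l - \alpha\,\nabla E(\theta_l)
  + \gamma\,(\theta_l - \theta_{l-1}),$$

with learning rate $\alpha = 0.001$ (constant; no schedule, no early
stopping), momentum $\gamma = 0.9$, mini-batches of 5 images, and a
fixed stop of 150 epochs. The printed update rule we implement restores
the learning rate multiplying the gradient; without it the configured
$\alpha$ would be inert. The loss is unweighted per-pixel cross-entropy
through the softmax. Mini-batch order is reshuffled every epoch from a
per-epoch seed; dropout masks are seeded per iteration, so a (data,
seed) pair reproduces its loss trace exactly.

Batchnorm uses batch statistics during training and running statistics
(momentum 0.1, epsilon 1e-5) at inference, so prediction is
deterministic. Ties at exactly 0.5/0.5 in the output probabilities go to
the background class.

Two execution paths compute the same model. The *reference path* walks
the graph layer by layer in double precision from R; it is the readable
specification of the semantics and what the finite-difference gradient
checks exercise. The *engine path* interprets the same graph in C++ with
single-precision activations and parameters — the customary precision
for CNN optimization — with batched im2col + GEMM convolutions and
persistent buffers. The test suite holds the two paths to agree on loss
traces (to about 1e-4 over a few iterations) and the engine is the
default for `trainNetwork()`.

### Data protocol

The data protocol is 60/20/20 stratified train/validation/test with
`val = test = round(0.2 n)` and the remainder training — the unique
simple rounding rule that reproduces the canonical subset sizes 233/77/77
(n = 387) and 97/33/33 (n = 163) — with per-class allocation by largest
remainder, so every class is represented within one item of its global
proportion. Model selection uses the validation set; the chosen
architecture is then assessed by stratified 5-fold cross-validation over
the merged training + test pool. Model comparison uses the
pooled-variance two-sample t statistic with $df = n_1 + n_2 - 2$ and a
two-tailed decision against `tCritical(confidence, df)`; the pooled
form (not Welch) is identified by that df convention. We compute exact
t quantiles; published shorthand values that disagree with the exact
quantile at the stated df (e.g. 1.982 at df 152, or a 95% label on the
99% df-8 value 3.355) are not reproduced.

## The synthetic phantom generator

The two clinical datasets behind this line of work are private, so the
package ships a seeded phantom generator that emulates the properties
the segmentation task actually depends on:

- **Geometry.** A lesion is a star-shaped radial contour
  $r(\theta) = r_0 + \sum_j a_j\cos(k_j\theta + \phi_j)$ plus, for
  malignant lesions, narrow Gaussian bumps in $r(\theta)$ (spicules,
  angular width 0.07 rad) at seeded random angles. Benign lesions are
  perturbed ellipses (harmonic amplitudes capped at $0.08\,r_0$, no
  spicules); malignant lesions carry at least 4 spicules plus higher
  harmonics. Solidity (area over convex-hull area) separates the two
  populations by at least 0.05 on average, which the tests assert.
- **Appearance.** Lesions are hypoechoic: the clean scene has background
  level 0.55 and lesion level `0.55 * contrast` with `contrast < 1`. A
  Gaussian-blurred noise field adds coarse tissue texture, multiplicative
  gamma noise with mean 1 and shape `1/speckleScale^2` models fully
  developed speckle, and a final Gaussian blur stands in for the system
  point-spread function. With `speckleScale = 0, blurSigma = 0` the
  render degenerates to the exact two-level scene, a property the tests
  use as the noise-free anchor.
- **Population.** `generateDataset()` draws per-item parameters
  (centre 0.42–0.58, base radius 0.10–0.18 of the image side, i.e.
  roughly 3–10% of pixels; malignant spicule count 4–8, relative length
  0.3–0.6) from per-item seeds derived splitmix-style from one master
  seed, so item *i* is reproducible independently of how many items are
  generated. The default class mix is 179 malignant : 208 benign in 387,
  mirroring the class balance of a representative clinical BUS
  collection. Rendering defaults are `contrast = 0.5`,
  `speckleScale = 0.3`, `blurSigma = 1`; no quantitative lesion-size or
  contrast statistics are published for the clinical data, so these are
  the package's own choices of a realistic operating point, fixed once
  and exposed as configuration.

What the phantoms deliberately do not model: attenuation and acoustic
shadowing, ribs/pectoral muscle and other anatomy, beam-profile
artifacts, 3-D volumes. Passing the end-to-end tests therefore shows
that the architectures, optimizer, metrics and protocol work as
specified on speckled hypoechoic lesions with the right margin
morphology — it does not certify clinical performance.

## Evaluation metrics

With label 1 = lesion as positive class and counts TP/FP/FN/TN:

- global accuracy $(TP+TN)/(TP+TN+FP+FN)$; mean per-class accuracy
  averages the two class recalls;
- per-class IoU $TP/(TP+FN+FP)$ and $TN/(TN+FN+FP)$, their mean, and a
  weighted IoU mixing the class IoUs by the gold mask's class
  proportions. The background weight uses background pixel counts, so
  the two weights sum to one (the printed weight formulas repeat the
  lesion count; the stated purpose of the metric requires
  class-proportion weights). Weights come from the gold mask, the
  standard convention;
- Dice $2TP/(2TP+FN+FP)$, algebraically $2\,\mathrm{IoU}/(1+\mathrm{IoU})$
  of the lesion class;
- boundary-F1: boundaries are lesion pixels 4-adjacent to background (or
  on the image border); precision/recall count boundary pixels within a
  Euclidean tolerance of the other mask's boundary, defaulting to
  `ceiling(0.0075 * image diagonal)` pixels; the score is the harmonic
  mean $2PR/(P+R)$ (the printed formula $2(P+R)/(P+R)$ is identically 2
  and is read as the stated "weighted harmonic mean"), 0 when $P+R=0$.

Metrics with an empty denominator (e.g. mean accuracy when the gold mask
has no lesion) are reported as flagged `NA` and excluded from set means
rather than silently coerced to 0 or 1. Set summaries are computed per
image and then averaged — whether published table means average images
or pool pixels is unstated, and the per-image convention is noted in the
report. `overlayErrors()` renders false positives pink, false negatives
green, true positives white and true negatives black.

## Numerical choices and degenerate inputs

- Batchnorm epsilon 1e-5, running-statistics momentum 0.1.
- Max-pool ties resolve to the first pixel in scan order; the
  size-preserving pool pads bottom/right implicitly with $-\infty$.
- Softmax and the loss are computed jointly in log-space.
- Zero pooled variance in the t test returns t = 0 for equal means and a
  flagged infinite statistic otherwise.
- Degenerate masks: empty contours refuse to rasterize; empty boundary
  sets give BF score 0 (one side) or `NA` (both); `predictMask` ties go
  to background.
- Masks are stored as 8-bit PNG with 255 = lesion; any nonzero pixel
  reads back as lesion. Images resize bilinearly, masks by nearest
  neighbour.

## Problem sizes used by the tests and the acceptance script

The published experiments train 52–68-layer, width-64 networks for 150
epochs on hundreds of 160- or 320-pixel clinical images — several GPU
hours per model — and their table values depend on the private data, so
they are not reproduction targets. The package's own experiments are
desk-scale by design: the end-to-end recovery experiment trains width-16
CNN3 on 200 synthetic 64-pixel phantoms for 30 epochs and requires mean
held-out Dice of at least 0.80 on 40 fresh phantoms in at least 4 of 5
seeds; the matched-budget series-versus-DAG comparison trains width-16
CNN1 and CNN3 on 60 spiculated phantoms for 12 epochs and compares mean
boundary-F1 on 12 held-out phantoms (an exploratory check, not a gate).
Structural checks (layer counts, shape conservation at 160 and 320,
split sizes, critical values, gradient agreement) are exact and fast.

## Known limitations

- The phantom generator's realism gap (above) bounds what green tests
  mean for clinical images.
- Skip-branch internals beyond CNN2's are reconstructed under a uniform
  rule; other compositions with the same tap points are possible.
- Single-precision training means two machines can differ in the last
  float digit of a loss trace; seeds fix everything else.
- No class weighting in the loss; strongly imbalanced external datasets
  may need it.
- No data augmentation, learning-rate schedule or early stopping, by
  protocol.
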