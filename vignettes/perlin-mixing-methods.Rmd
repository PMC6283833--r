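---
title: "Perlin-noise patch mixing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perlin-noise patch mixing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perlintex)
```

## The augmentation model

Small labeled patch datasets overfit quickly. The strategy implemented here
blends **two** labeled patches along the sign boundary of a random smooth
field: generate 2D simplex noise the size of the patch, call the
non-negative region one mask and its complement the other, and take pixels
(and labels) from patch A inside the mask and from patch B outside. The
result is a mixed-class patch with a **per-pixel** label grid whose
boundary geometry is random but spatially coherent — unlike pixel-wise
noise, and unlike rectangular cut-and-paste mixing, the transition follows
a natural-looking contour. With 480 training patches the number of distinct
(pair, mask) combinations is effectively unlimited.

### Simplex noise

The generator is the standard 2D simplex scheme: skew the query point onto
a triangular lattice, locate the three corners of the containing triangle,
and sum per-corner contributions `(0.5 − d²)₊⁴ (g·d)` where `d` is the
distance vector to the corner and `g` a gradient hashed from a seeded
permutation table into the classic 12-direction set (the 2D projections of
the twelve cube-edge vectors; four directions appear twice by design). The
sum is multiplied by the reference normalisation constant 70: the analytic
maximum of the unscaled sum lies just above 1/70.14, so 70 keeps sampled
magnitudes below 1 — the suite verifies the bound over 10⁴ random points,
and a 50-point probe set is checked against an independent scalar
transcription of the reference algorithm at 10⁻⁹.

Seeding is one documented shuffle: the permutation is `sample.int(256) - 1`
under R's Mersenne–Twister seeded with the table seed, and every stochastic
operation in the package runs under a save/restore wrapper so nothing leaks
global RNG state. Child seeds derive from a master seed by the MINSTD
congruence `(seed · 48271 + index) mod (2³¹ − 1)`, which stays exact in
double arithmetic.

### Tunable noise parameters

* `scale` (input units per pixel, default **0.1**) — the field's feature
  size. The study that motivated this package does not report its noise
  frequency, so the default was chosen once so that a 20-pixel patch spans
  roughly two feature periods, giving coarse two-region masks rather than
  salt-and-pepper fragments; it is exposed everywhere a mask is made.
  Masks average a 50/50 sign split (checked over 1000 seeds, mean
  true-fraction within [0.45, 0.55]).
* `octaves` (default **1**) — fractal summation at frequency 2ᵒ and
  amplitude 2⁻ᵒ, renormalised by the total amplitude so the [−1, 1] bound
  survives. The single-octave default matches the mask appearance the
  blending strategy calls for; multi-octave fields are supported for
  exploration.
* Exact zeros in the field (they occur at lattice corners) go to the
  positive mask region — a measure-zero tie needing only a fixed,
  documented rule.
* Pair sampling draws two **distinct patches** uniformly; their classes may
  coincide. A same-class blend is a harmless identity at the label level,
  and excluding it would bias the pair distribution. Whether masks must
  have two non-empty regions is parameterised (`require_nonempty`,
  default off).

### The conventional baseline

Both augmentation modes first flip the patch up–down and left–right, each
with independent probability ½. Conventional mode then adds i.i.d.
zero-mean Gaussian noise with σ equal to **one tenth of the patch's own
standard deviation**; the population divisor (n, not n − 1) is fixed so
outputs are bit-reproducible — at 400 pixels the numerical difference is
negligible, but a single convention must be chosen. Perlin mode replaces
the noise step with mask blending. Flips precede masking, matching the
stated order of the original procedure.

## The synthetic fixture generator

The HRCT ROIs behind the original study are not deposited, so the test
dataset is synthetic: 100 patches per class × 6 classes of 20 × 20 pixels,
HU-like intensities in [−1000, 400]. Each class is a base attenuation
level plus Gaussian speckle plus a structural element caricaturing the
radiological pattern:

| class | level (HU) | speckle σ | structure |
|---|---|---|---|
| normal | −870 | 35 | none |
| GGO | −570 | 55 | smooth blobs (±80) |
| consolidation | 30 | 40 | none |
| RO | −720 | 45 | fine bright lines (+330) |
| emphysema | −810 | 40 | low-attenuation holes (−180) |
| honeycombing | −780 | 45 | walled rings (+550) |

Structural contributions are centred to zero mean before use, so a patch's
expected mean equals its class level exactly and the per-class levels are
directly interpretable. The parameterisation ships in
`inst/extdata/texture-specs.yaml` and is overridable.

What the generator emulates: class-distinguishable first- and second-order
statistics, spatial structure at class-typical scales, a fixed intensity
window. What it does **not** emulate: scanner noise correlation,
partial-volume effects, transitional zones between patterns, anatomical
context (vessels, airways), or the intra-class heterogeneity of real
disease. Tests passing on these fixtures therefore demonstrate that the
pipeline's mechanics are correct and that training is learnable — they do
not certify accuracy on real HRCT, and no directional claim about which
augmentation wins on real data is asserted at this scale.

## The classifier

The per-pixel classifier is a deliberately scaled-down encoder–decoder of
the FusionNet/U-Net family, written in base R matrix algebra (im2col
convolutions): encoder levels of 4 × 4 convolutions with an additive
residual 4 × 4 block and 2 × 2 max-pooling, a convolutional bottleneck, a
decoder of nearest-neighbour upsampling and 4 × 4 convolutions with
additive encoder→decoder skip connections, and a final 1 × 1 convolution
to six softmax logits per pixel. Defaults: **depth 2, base_filters 8**
(~18k parameters). The architecture family — residual blocks, skips,
4 × 4 kernels, batch size 16 — follows the original design; the width is a
desk-scale choice so a full training run takes about a minute on one CPU,
and the depth/filter counts of the original network are not published in
any case.

Training: pixel-wise cross-entropy under Adam (learning rate 2 × 10⁻³,
β = 0.9/0.999), batches of 16 freshly augmented patches per step, inputs
window-normalised from [−1000, 400] to [0, 1]. Held-out pixel accuracy is
evaluated every 25 steps on the untouched test split (no augmentation is
ever applied to it); training stops after 6 evaluations without
improvement or at 600 steps, and the best-evaluation parameters are
returned, so the fitted model's held-out accuracy equals the maximum in
its history by construction. A non-finite loss aborts with the step index.
The 20% held-out set serves both as the early-stopping validation set and
as the reported test set — the same dual use as the protocol this package
follows; a separate three-way split was considered and rejected as the
default because at 600 patches a third partition would leave only ~60
patches per role, and the design question the package answers (do the
augmentation mechanics work end to end) does not hinge on an unbiased
final estimate.
Everything is seeded and single-threaded; two runs with the same seeds are
bit-identical.

Numerical details worth stating:

* 4 × 4 "same" convolutions use zero padding of 1 before and 2 after in
  each dimension (offsets −1…2).
* An input side indivisible by 2^depth is reflect-padded to the next
  multiple and the output cropped back; the default depth-2 model on
  20 × 20 patches needs no padding (20 → 10 → 5 under two pools).
* Max-pool ties resolve to the first corner in scan order; argmax label
  ties resolve to the lowest class index; both rules are exercised by
  tests (an all-zero-parameter model predicts class 0 everywhere).
* Biases initialise at zero and weights He-normal; backpropagation is
  verified against central finite differences at 10⁻⁴ relative error
  (after jittering parameters off exact ReLU kinks, where a subgradient
  and a central difference legitimately differ).

## Evaluation

`pixel_accuracy()` implements the per-pixel fraction-correct statistic;
`per_class_table()` reports each class over the pixels whose *truth* is
that class, so the pixel-weighted per-class average reproduces the overall
mean exactly (asserted at 10⁻⁹), and a class absent from the truth is
reported as undefined (`NA`), never 0. Paired comparisons between
augmentation modes use the per-ROI accuracies of identical test patches —
the only pairing unit consistent with the accuracy formula — via the
standard paired t-test, with degenerate cases flagged instead of crashing
(all-zero differences: t = 0, p = 1; constant non-zero differences:
infinite t). Whole-image quantification slides a tile window (default
stride = tile/2, both exposed), sums softmax probabilities over
overlapping tiles and takes the argmax; pixels outside the foreground
mask are labeled `NA` and excluded from any accuracy. Dense per-pixel
inference is the stride-1 special case.

## Problem sizes

The shipped defaults are the package's study conditions: 600 fixture
patches (100 per class), an 80/20 stratified split (480/120, 20 test
patches per class), 600 training steps of batch 16, evaluation every 25
steps, patience 6. Bound and balance invariants are checked over 10⁴
sampled points and 10³ seeds respectively. At these sizes the complete
test suite and the acceptance script each finish in minutes on a single
CPU.

## Known limitations

* The synthetic textures are caricatures; accuracy numbers obtained on
  them say nothing quantitative about real HRCT, and the original study's
  accuracy tables are out of reach without its data.
* The classifier is narrow (8 base filters) and trained briefly;
  conventional-mode and perlin-mode accuracies on the fixtures are
  reported side by side without asserting a direction.
* Only binary two-patch masks are implemented — no soft alpha blending,
  no >2-source mixes, no 3D noise.
* Bit-reproducibility holds within a fixed BLAS/platform; across platforms
  results agree to floating-point tolerance only.
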