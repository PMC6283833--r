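# perlintex

Data augmentation for small labeled image-patch datasets by **Perlin-noise
patch mixing**, with an end-to-end harness for six-class lung texture
classification.

## The problem

Pixel-wise classifiers for diffuse interstitial lung disease (DILD) patterns
on HRCT — normal parenchyma, ground-glass opacity (GGO), consolidation,
reticular opacity (RO), emphysema, honeycombing — are typically trained from
a few hundred expert-labeled 20 × 20-pixel regions of interest (ROIs).
With so little data, augmentation decides whether training works at all.
The idea implemented here: generate 2D **simplex (Perlin) noise** the size of
an ROI, split the patch into the noise's positive and negative sign regions,
and stitch **two** randomly chosen labeled ROIs together along that random,
natural-looking boundary. Each augmented patch carries a per-pixel label
grid, so a single pair of ROIs yields an effectively unlimited supply of
mixed-pattern training patches — much closer to real parenchyma, where
disease patterns interleave, than single-class patches ever are.

Simplex noise at a point is the sum over the three corners of the containing
lattice triangle of

```
(0.5 − d²)₊⁴ · (g · d)
```

where `d` is the corner-to-point distance vector and `g` a pseudorandom
gradient from a fixed 12-direction set, scaled by 70 so values lie in
[−1, 1]. The noise is seeded through a 256-entry permutation table, so every
mask is reproducible.

The per-pixel classification accuracy of a classifier over `N_ROI` test
patches of `N_x × N_y` pixels is

```
Accuracy = 100 / (N_x · N_y · N_ROI) · Σᵢ Σⱼ Σₖ [pred(R_ijk) = true(R_ijk)]  (%)
```

and two augmentation strategies are compared by a paired t-test on per-ROI
accuracies.

Because the original HRCT ROIs are not publicly deposited, the package ships
a synthetic six-class texture generator with class-separable statistics
(attenuation level, speckle, blobs/lines/rings/holes) as its fixture
dataset, and a deliberately scaled-down encoder–decoder per-pixel classifier
(4 × 4 convolutions, residual blocks, max-pooling, skip connections,
softmax) written in base R, trainable on one CPU in about a minute.

## Worked example

```r
library(perlintex)

data  <- generate_dataset(100, seed = 42)        # 600 patches, 100 per class
split <- stratified_split(data, 0.2, seed = 1)   # 480 train / 120 test

# one augmented batch the way training consumes it
batch <- make_batch(split$train, 16, mode = "perlin", seed = 7)
print(batch[[1]])
#> <aug_patch> 20 x 20; labels: consolidation=197, ro=203

fit <- ptex_train(split, train_config = train_config(seed = 1))
print(fit)
#> <ptex_fit> perlin augmentation, 600 steps, best held-out pixel accuracy 94.1%

preds  <- lapply(predict_patch(fit$model, split$test), `[[`, "labels")
truths <- lapply(split$test$patches, function(p) matrix(p$label, 20, 20))
print(per_class_table(preds, truths))
#> <evaluation_report> 120 ROIs of 20 x 20
#>   normal          99.9%
#>   ggo            100.0%
#>   consolidation  100.0%
#>   ro              87.2%
#>   emphysema       95.7%
#>   honeycombing    81.7%
#>   mean            94.1%
```

The per-class rows are pixel accuracies over the 20 held-out ROIs of each
class; `mean` is the pixel-weighted aggregate over all 120 × 400 test
pixels. A second run with `augmentation_mode = "conventional"` (random
flips + Gaussian noise at one tenth of the patch standard deviation) gives
the baseline, and `paired_t()` compares the two per-ROI accuracy vectors.

A command-line interface covering fixture generation, augmentation,
training, evaluation and comparison is installed as `exec/perlintex`
(subcommands `generate-fixtures`, `augment`, `train`, `evaluate`, `compare`,
`noise-preview`).

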