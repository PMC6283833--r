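Package: perlintex
Title: Perlin-Noise Patch-Mixing Augmentation for Lung Texture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data augmentation for small labeled patch datasets by blending two
    patches through the sign mask of seeded two-dimensional simplex (Perlin)
    noise, producing mixed patches with per-pixel class labels. Includes a
    from-scratch seeded simplex noise generator, the conventional
    flip-plus-Gaussian augmentation baseline, a synthetic six-class lung
    texture fixture generator emulating HRCT regions of interest, stratified
    dataset splitting and plain-text patch archives, a scaled-down
    encoder-decoder per-pixel classifier with seeded training and early
    stopping, and pixel-by-pixel accuracy evaluation with per-class tables,
    paired t comparison and tiled whole-image quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
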