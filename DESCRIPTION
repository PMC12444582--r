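Package: HaralickScaling
Title: Scaling Laws and Bit-Depth Normalization for GLCM Haralick
    Texture Features
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes gray-level co-occurrence matrices (GLCMs) and four
    Haralick texture features (Energy/ASM, Contrast, Correlation,
    Homogeneity/IDM) together with closed-form analytic predictions of
    these features for images containing one-dimensional linear
    gray-level gradients. The analytic scaling laws describe how each
    feature depends on the number of gray levels, the gradient
    magnitude, and the probing displacement, and yield normalization
    factors that make the features asymptotically invariant to image
    bit depth. Includes a synthetic sawtooth-gradient image generator,
    PNG/TIFF import/export, gradient estimation by inverting the
    Energy law, and a validation harness that sweeps gradients and
    displacements to compare measured features against analytic
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    tiff,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
biocViews: Software, Visualization, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
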