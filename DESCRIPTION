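Package: ktlps
Title: Low-Rank Plus Sparse Reconstruction of Dynamic MRI from Undersampled k-t Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs dynamic (2D+time) magnetic resonance image series from
    undersampled k-t space measurements by decomposing the spatiotemporal Casorati
    matrix into a low-rank background plus a sparse dynamic component (robust
    principal component analysis), solved with an inexact augmented Lagrange
    multiplier scheme built on singular value thresholding and complex
    soft-thresholding. Includes Cartesian variable-density and pseudo-radial
    sampling-mask generators, the masked unitary Fourier encoding operator with a
    complex Gaussian noise model, energy-normalized PSNR and global SSIM quality
    metrics, a synthetic dynamic phantom with planted rank and sparsity, and a
    seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    generics,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    RNifti,
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
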