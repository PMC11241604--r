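Package: lungscreen
Title: Lung-Carcinoma Screening on Chest Images with Adaptive Diffusion,
    Coati-Seeded Region Growing and a Parametric-ReLU Residual Classifier
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screening pipeline for lung carcinoma on 2-D grayscale chest
    images: structure-adaptive anisotropic diffusion denoising driven by
    intra-class variance, contrast stretching and convex-hull lung-field
    extraction, unsharp-mask edge enhancement, region-growing segmentation
    seeded by a Bates-distributed coati optimization metaheuristic,
    engineered gradient/spectral/profile/on-rib/on-vessel features,
    chi-square feature selection with a binomially derived significance
    level, a small residual network with parametric ReLU for
    normal/abnormal classification, and a high/low risk screen based on
    on-rib evidence. Includes a synthetic chest-phantom generator with
    full ground truth so every stage is testable without external data,
    and the usual evaluation metrics (confusion-matrix rates, Dice,
    MSE/PSNR/SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, Segmentation, Preprocessing
RoxygenNote: 7.3.3
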