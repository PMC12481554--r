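Package: stripgan
Title: Attention-Augmented Wasserstein GAN Data Augmentation for
    Lateral Flow Immunoassay Strip Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for training image classifiers of lateral flow
    immunoassay (LFIA) test strips when real photographs are scarce. The
    package procedurally simulates class-labelled strip images, implements
    the standard LFIA preprocessing chain (edge crop, zero padding,
    line-based crop, rotation augmentation), trains a Wasserstein GAN whose
    generator and critic carry a direct spatial self-attention block,
    filters generated images by structural similarity (SSIM) and perceptual
    hash Hamming distance, assembles real/synthetic training mixtures, and
    evaluates three-class concentration classifiers with confusion
    matrices, per-class sensitivity/specificity/PPV/NPV, one-vs-rest ROC
    curves and t-SNE embeddings. All neural networks are implemented in R
    with exact hand-derived gradients so the whole pipeline runs
    deterministically on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    png,
    yaml,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
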