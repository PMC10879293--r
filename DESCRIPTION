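Package: SupConFewShot
Title: Supervised Contrastive Pre-Training for Few-Shot Plant Disease
    Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-phase few-shot image classification for plant disease
    leaf imagery. Phase 1 pre-trains a convolutional encoder with a
    supervised contrastive loss (temperature-scaled cosine similarity,
    label-aware positive sets) on two stochastically augmented views per
    image. Phase 2 freezes the encoder and performs N-way K-shot
    recognition with a nearest-centroid (prototype) classifier under a
    squared-Euclidean softmax, reporting episodic top-1 accuracy with
    95 percent confidence intervals and cumulative confusion matrices.
    Includes the four-operator augmentation pipeline (random resized
    crop, horizontal flip, color distortion, random grayscale), a seeded
    generator of class-structured leaf-like images for desk-scale
    experiments, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
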