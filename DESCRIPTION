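Package: ProtoDS
Title: Prototypical Networks with Contrastive Pretraining and Dice Loss for
    Imbalanced Hyperspectral Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies physical instances imaged by near-infrared
    hyperspectral cameras under severe class imbalance. Implements the
    two-step Proto-DS training scheme: instance-wise spectral contrastive
    pretraining of a batch-normalised embedding network over unlabeled pixel
    spectra, followed by episodic fine-tuning of a prototypical classifier
    with a combined Dice and cross-entropy objective. Includes dark/white
    reference calibration of ENVI-style reflectance cubes, effective-pixel
    masking, band cropping, a seeded synthetic-cube generator emulating the
    statistical structure of NIR instance data, an imbalanced-learning
    evaluation harness (balanced accuracy, macro F1/AUROC/AP, per-class
    sensitivity and specificity, ratio-scaled minority downsampling), an
    ablation runner, and a PCA Gaussian-overlap separability diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
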