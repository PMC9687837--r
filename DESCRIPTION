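Package: InResECG
Title: Paper-Based ECG Sheet Preparation, Quality Assurance and Hybrid
    Inception-ResNet Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for classifying scanned paper electrocardiogram (ECG)
    sheets. Provides a synthetic sheet generator with ground-truth signal,
    grid and label masks; an artifact-removal pipeline (automated label
    cropping, Otsu binarisation, morphological opening, connected-component
    gridline filtering, inversion, Gaussian blur, non-local-means denoising)
    followed by histogram equalisation; image-quality assurance (MSE, RMSE,
    PSNR, SSIM and PSNR binning reports); manifest handling with stratified
    70:20:10 splitting and k-fold partitioning; a configurable hybrid
    Inception-ResNet convolutional network with parametric ReLU and a
    learnable residual scaling factor, including layer and multiply-accumulate
    accounting and training/evaluation drivers; a greedy ablation-study
    harness with an accuracy-versus-complexity selection rule; and a full
    evaluation suite (one-vs-rest confusion-matrix metrics, Matthews
    correlation, Cohen's kappa, exact Wilcoxon signed-rank, ROC/AUC and
    k-fold cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
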