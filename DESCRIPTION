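Package: hetMCET
Title: Minimum Cross Entropy Thresholding with Heterogeneous Mean Estimators
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bilevel grayscale image segmentation by minimum cross entropy
    thresholding (MCET) in which the two region means of the objective are
    estimated by heterogeneous pairs of histogram-domain mean filters
    (classical, geometric, harmonic, contra-harmonic, alpha-trimmed).
    Includes the full enumeration of heterogeneous and homogeneous
    estimator configurations, exhaustive threshold search, unsupervised
    (uniformity, region contrast, inter-region disparity) and supervised
    (Jaccard, F-score, accuracy) segmentation evaluation with best-threshold
    selection, a bimodal phantom generator with ground truth for controlled
    noise experiments, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Segmentation, Thresholding, Software
RoxygenNote: 7.3.3
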