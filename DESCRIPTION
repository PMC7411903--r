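Package: ipfcm
Title: Intuitionistic-Possibilistic Fuzzy C-Means Segmentation and Fuzzy-SVM
    Classification of Breast Masses
Version: 0.1.0
Authors@R:
    person("Mammogram", "Segmentation Toolkit", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Fuzzy clustering algorithms for lesion segmentation in grayscale
    mammograms: fuzzy c-means (FCM), possibilistic FCM (PFCM), intuitionistic
    FCM (IFCM) and the hybrid intuitionistic-possibilistic FCM (IPFCM), plus an
    Otsu thresholding baseline. Includes region-of-interest shape descriptors
    (radial-length profile, circularity, shape factor, spiculation statistics)
    and gray-level-histogram texture moments, a fuzzy-weighted support vector
    machine classifier with a Gaussian kernel, confusion-matrix and ROC/AUC
    evaluation metrics, a seeded phantom-mammogram generator with ground truth
    for benchmarking under salt-and-pepper noise, and command-line pipeline
    drivers. Reads and writes PGM images natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
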