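Package: pycnoseg
Title: Segmentation and Counting of Pycnotic Nuclei in Brain Slice Culture Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable pixel classification for counting propidium-iodide
    positive (pycnotic, dead-cell) nuclei in fluorescence z-stacks of
    organotypic brain slice cultures. Builds a 116-channel spatial feature
    bank (Gaussian derivatives, Laguerre-Gauss filters, structure-tensor
    coherency, top-hat and local-entropy transforms), de-correlates it with
    PCA, ranks components by Wilcoxon rank-sum tests and trains naive Bayes,
    quadratic discriminant, random forest and multilayer perceptron pixel
    classifiers. Whole stacks are routed to damage-specific models by a
    bag-of-visual-words support vector machine, and predicted masks are
    cleaned morphologically, screened by a morphology-feature SVM and split
    into individual nuclei with a circular Hough transform. Includes a
    synthetic stack generator so the full pipeline is testable without
    microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    Rcpp,
    e1071,
    grDevices,
    jsonlite,
    nnet,
    randomForest,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
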