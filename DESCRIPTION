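Package: frameclust
Title: Unsupervised Informative Frame Selection for Endoscopic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised selection of informative frames from endoscopic
    (narrow-band imaging) video. Frames are embedded with a fixed random-weight
    convolutional network or a fast pixel backend, projected to a
    low-dimensional space (PCA, t-SNE or UMAP), grouped with one of four
    clustering families (mini-batch k-means, agglomerative, spectral, DBSCAN),
    and the clusters are automatically aligned to semantic quality categories
    (blurred, informative, specular/saliva, underexposed) by a
    maximum-intersection bijection. Includes bespoke cost functions for
    hyperparameter search by Bayesian optimization or random search,
    clustering-as-classifier evaluation (precision/recall/F1, one-vs-rest
    ROC/AUC, exact paired Wilcoxon tests), internal validity indices
    (Calinski-Harabasz, silhouette) for cluster-number determination, and a
    synthetic frame generator emulating the four quality categories so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    jsonlite,
    png,
    lhs,
    uwot,
    Rtsne,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
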