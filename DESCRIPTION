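Package: chromaphen
Title: High-Throughput Chromatin Phenotyping of Nuclei in Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A supervised image-analysis pipeline for quantifying chromatin
    organisation of plant nuclei in two-channel fluorescence microscopy time
    courses. Simulates benchmark image sets with ground truth, performs maximum
    intensity projection, retrospective illumination correction and ranged-Otsu
    nucleus segmentation, extracts a 370-feature registry per nucleus
    (morphology, intensity, and multiscale texture: local binary patterns,
    threshold adjacency statistics, Gabor filters and Hu moments), rejects
    mis-segmented objects with a support vector machine, and analyses chromatin
    heterogeneity by principal component analysis with SVD imputation and by
    discretised Shannon entropy of single-nucleus feature distributions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
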