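Package: neuroquant
Title: Quantification of Fluorescence Imaging Assays in iPSC-Derived Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and signal-derived quantification for immunofluorescence
    and live-imaging assays of cultured neurons. Provides calibrated image
    primitives (automatic histogram thresholding, particle filtering, hole
    filling, watershed splitting, region morphometry), fixed quantification
    recipes for C9orf72 intensity, TDP-43 cytosol-to-nucleus ratio,
    p62/SQSTM1 vesicles, gamma-H2A.X foci and RNA-FISH foci per nucleus,
    nuclear morphometry with micronucleus detection and two-group K-means
    splitting of nuclear areas, a parameterized dendritic-spine detector and
    mushroom/stubby/thin classifier for calibrated 3D stacks, delta-F-over-F0
    calcium transient analysis with stimulus-response gating, and a
    normality-gated statistics ladder with post-hoc comparisons and robust
    outlier screening. Ground-truth synthetic fixture generators emulate
    every supported input so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
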