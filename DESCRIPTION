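Package: boutonfinder
Title: Automated Detection of Axonal Boutons in Fluorescence Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects presynaptic axonal boutons of single traced neurons in large
    3D fluorescence microscopy volumes. A manually traced skeleton (SWC) guides
    redundant division of the axonal arbor into segments and extraction of tubular
    sub-volumes; foreground signal is segmented by adaptive binarization against a
    smoothed background estimate followed by mild morphological erosion; candidate
    swelling centers are located by density-peak clustering on the foreground
    intensities; and a compact residual convolutional network classifies image
    patches around each candidate to reject non-bouton axonal swellings. Includes
    a seeded synthetic axon-scene simulator with ground-truth swelling tables, a
    distance-tolerance matched-detection evaluation protocol (precision, recall,
    F1), and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
NeedsCompilation: yes
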