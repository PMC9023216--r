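Package: otoseg
Title: One-Two-One Fully Convolutional Networks for Intracranial Aneurysm Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated segmentation of intracranial aneurysms in
    time-of-flight magnetic resonance angiography (TOF-MRA) volumes. Implements
    block-based 3D preprocessing with disequilibrium culling of lesion-free
    training blocks, a one-two-one (OTO) cascade of three encoder-decoder fully
    convolutional structures with residual additions and stacked skip
    connections, loss ensembles (Dice plus cross-entropy and Dice plus boundary
    loss via signed distance maps), surface-distance evaluation metrics (Dice
    similarity coefficient, average surface distance, 95th-percentile Hausdorff
    distance), and a synthetic vascular phantom generator so the whole pipeline
    can be exercised end to end without clinical data. The 3D convolution
    engine (forward, backpropagation, Adam) is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
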