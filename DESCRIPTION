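Package: voxrecon
Title: Self-Supervised Reconstruction and Semantic Decoding of Seen Images
    from Voxel Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains an image-to-voxel encoder and a voxel-to-image decoder
    for reconstructing seen images from voxelwise brain responses. The
    decoder is trained with cycle-consistent self-supervision on unpaired
    natural images, combining pixel, perceptual-similarity and total
    variation losses. Includes category-free semantic classification of
    reconstructions against deep-feature class centroids, evaluation tools
    (n-way identification, rank classification, split-half noise ceilings,
    noise-corrected voxel prediction accuracy), population receptive field
    estimation by gradient and weight methods with retinotopy summaries,
    and a procedural virtual-subject simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
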