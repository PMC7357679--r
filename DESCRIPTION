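Package: seadapt
Title: Semi-Supervised Domain Adaptation for Multispectral Benthic Habitat
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Patch-based classification of multispectral satellite scenes
    into benthic habitat classes (seagrass, sea, sand, land, intertidal),
    with a two-step semi-supervised domain adaptation procedure for
    transferring a classifier trained at one site to another: adversarial
    alignment of the marginal embedding distributions using unlabeled
    pixels from both sites, followed by few-shot contrastive semantic
    alignment that jointly re-optimizes the source and target embedding
    functions from a handful of labeled target pixels.  Includes raster
    and label-mask input/output, a compact convolutional embedding model
    with exact gradients, a synthetic domain-shift scene generator for
    benchmarking, radiometric calibration of imagery against in situ
    optical stations, stratified cross-validation, scene-wide
    classification maps, and t-SNE embedding export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
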