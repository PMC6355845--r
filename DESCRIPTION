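Package: mobia
Title: Object-Based Image Analysis for Cold-Water Coral Mound Facies Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for mapping cold-water coral mound facies from
    co-registered seabed imagery: multiresolution region-merging segmentation
    of a video mosaic into objects, per-object spectral, texture (grey-level
    co-occurrence), shape and bathymetric terrain features, supervised
    classification of objects into benthic facies with multinomial logistic
    regression, random forests and a multilayer neural network, accuracy
    assessment with micro- and macro-averaged metrics, and post-classification
    spatial statistics (zonation area tables, Getis-Ord Gi* hotspot fields,
    hotspot-depth correlation, aspect polar histograms). Includes a seeded
    synthetic benthic scene generator (bathymetry, RGB mosaic, backscatter,
    ground-truth facies map, mound boundary) so the full pipeline can be run
    and tested end to end without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    nnet,
    ranger,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
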