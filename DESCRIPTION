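Package: pigback
Title: Pig Body-Weight Estimation from Overhead 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Hybrid denoising and body-weight estimation for pigs recorded by a
    single overhead depth camera. Point clouds are cleaned with a statistical
    k-nearest-neighbour outlier filter followed by DBSCAN density clustering,
    the pig's back is isolated, aligned and trimmed of head and tail using
    convex-hull sag analysis, and voxel-grid downsampling reduces resolution
    before back body-size features (envelope volume and area, projection area,
    shoulder/belly/hip widths) are extracted. Weight is regressed with a small
    convolutional neural network over a back height raster plus the feature
    vector, with a radial-basis-function network baseline. A synthetic
    overhead-scene generator with labelled noise and known ground-truth weight
    makes every stage testable without farm recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
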