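Package: exmtools
Title: Quantitative Image Analysis for Expansion-Gel Multiplexed Ion-Beam Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multiplexed ion-count images (MIBI/IMC) of
    physically expanded tissue gels. Implements perivascular anchoring
    profiling via one-pixel morphological step rings around segmented vessel
    objects, expansion-fold estimation by three concordant strategies (linear
    landmark ratios, tissue area, cell-size distributions), edge-spread
    resolution estimation by the 16-84 percent criterion, RMS distortion
    curves from pairwise feature-distance changes after affine plus nonrigid
    alignment, composite-channel segmentation of non-nuclear features, and
    sliding-window marker gradient profiles. Includes a synthetic phantom
    generator (vessels with concentric marker layers, cell fields, Poisson
    count noise, known scalings and smooth warp fields) providing ground
    truth for every analysis, and minimal readers and writers for
    single-channel grayscale TIFF stacks with panel metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
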