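Package: placodeQuant
Title: Quantitative Analysis of Apical Constriction in Epithelial Placodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying apical constriction during epithelial
    tube invagination from two-channel (junctional marker plus myosin
    reporter) microscopy images, modelled on the Drosophila embryonic
    salivary-gland placode. Provides watershed segmentation of apical cell
    outlines from junctional signals, invagination staging, apical-area
    distribution statistics with median-scaling normalization, pit-relative
    spatial dispersion and clustering permutation tests, junctional versus
    apicomedial myosin intensity partitioning, placode-boundary circularity
    as a tissue-tension proxy, and prominence-based detection of pulsatile
    apicomedial myosin with inter-pulse interval statistics. A synthetic
    placode generator (Lloyd-relaxed power-diagram tessellation, rendered
    channels with PSF blur and shot noise, pulsatile intensity traces)
    supplies ground truth for every measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
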