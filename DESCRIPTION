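Package: fatemapr
Title: Quantification of Tamoxifen-Timed Cre/lox Fate Mapping in the preBotzinger Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify Cre-driver fate-mapping experiments in the mouse
    preBotzinger complex: simulation of per-animal neuron/glia count cohorts and
    of 3-D fluorescence image stacks with ground truth; morphometric
    classification of labeled cells by soma cross-sectional area, including
    3-D connected-component segmentation and detection of the bimodal break in
    the pooled area distribution; a shuffle-and-resample significance test over
    tamoxifen-administration timepoints with 99% confidence bands and an
    exact-enumeration oracle; and stereological extrapolation of total neuron
    number from counts in a sampled test volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
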