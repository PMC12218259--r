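Package: caensemble
Title: Ensemble Encoding Analysis for Calcium-Imaging Event Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of how neuronal populations encode behavioral
    variables across contexts, from microendoscopic calcium-imaging data.
    Provides calcium-transient detection from dF/F traces (equiripple
    low-pass filtering plus amplitude/derivative/area thresholding),
    mask-based population activity vectors and Pearson similarity
    matrices, per-neuron modulation indices from circular-permutation
    null distributions, balanced linear support-vector-machine decoding
    with cross-condition transfer and degree-preserving surrogate
    rasters, ensemble orthogonality and overlap quantification
    (zero-centered cosine similarity with label-permutation nulls,
    3x3 overlap tables with chi-squared comparisons), and a synthetic
    session generator with planted per-neuron modulation for
    ground-truth validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    signal,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
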