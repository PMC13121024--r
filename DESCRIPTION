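Package: phidyn
Title: Integrated Information Decomposition, Network Control Energy and
    Whole-Brain Mean-Field Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies integrated information in multichannel brain-like
    timeseries via the Gaussian minimum-mutual-information integrated
    information decomposition (the 16 past-to-future information atoms and
    derived measures such as revised integrated information, whole-minus-sum
    integrated information, causal density and net information flow), relates
    it to minimum control energy on a weighted structural connectome via
    linear network control theory, and models it mechanistically with a
    dynamic mean-field simulator supporting transcriptomically weighted
    regional inhibition and nodal excitatory stimulation. Includes generators
    for vector-autoregressive timeseries, synthetic connectomes and null
    networks, spatially autocorrelated regional maps with Moran spectral
    randomization surrogates, and whole synthetic multi-subject studies, plus
    dominance analysis with permutation testing and spatially constrained
    correlation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
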