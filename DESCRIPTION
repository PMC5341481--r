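Package: nucleomark
Title: Position-Specific Markov Models of Nucleosome-DNA Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Position-dependent oligonucleotide Markov-chain models of
    nucleosome-DNA binding affinity, trained on ensembles of 147-bp
    nucleosomal sequences, together with genome-scale free-energy landscape
    computation and an RMSD-based benchmarking framework (uniform and
    phase-shifted "bad model" baselines, ensemble-size sweeps, smoothing and
    zero-probability policies). Includes a tractable quadratic ("toy")
    biophysical nucleosome model with a Mutation Monte Carlo sampler and
    exact Gaussian and transfer-matrix oracles, so that the approximation
    quality of the Markov models can be measured against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
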