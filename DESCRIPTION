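Package: SignalingHotspots
Title: Expression-Weighted Random-Walk Hotspot and TF-Compatibility
    Inference on Signed Signalling Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers sustained signalling "hotspots" from a signed directed
    signalling interactome and condition-specific gene expression. Each
    sample defines an expression-weighted Markov chain over the network;
    its stationary distribution ranks signalling intermediates, and
    candidate nodes are scored against a differential transcription-factor
    signature by sign-propagated shortest paths whose relative
    contributions are weighted by the stationary probabilities of the path
    interiors. Includes readers for SIF/TSV interactomes, TSV and
    MatrixMarket expression matrices, an optional TF-TF regulatory layer
    for signature TFs outside the interactome, a synthetic-scenario
    generator with planted driver and decoy cascades, and a two-condition
    comparison pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
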