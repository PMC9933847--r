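Package: netpu
Title: Positive-Unlabeled Labeling of Disease Genes by Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes on a protein-protein
    interaction network from a set of scored seed genes. Computes four
    seed-set-aware node features (graph-Laplacian heat diffusion,
    random-walk balanced diffusion, a score-weighted harmonic centrality
    and a ring-decomposition rank), then assigns five classes (positive,
    likely positive, weakly negative, likely negative, reliable negative)
    with an adaptive positive-unlabeled labeling algorithm driven by a
    Markov process with restart on a feature-similarity graph. Includes
    classifier-based evaluation, seed-masking rediscovery and ranked
    candidate evaluation protocols, a planted-module synthetic data
    generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    randomForest,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    withr
Config/testthat/edition: 3
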