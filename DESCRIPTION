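Package: manifoldDyn
Title: Two-Step Diffusion-Map Embedding of Multi-Subject Brain Dynamics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Embeds time-synchronized, multi-subject parcellated functional
    time series into a shared low-dimensional manifold with hierarchical
    two-step diffusion maps (2sDM), extends new time points onto the learned
    manifold with a two-step Nystrom out-of-sample extension after orthogonal
    BrainSync temporal alignment, and characterizes dynamics on the manifold:
    sliding-window connectivity from multiplication of temporal derivatives
    (MTD), time-resolved Louvain communities and participation coefficients,
    discrete brain states selected by the Calinski-Harabasz criterion, and
    Markov transition structure (stationary distributions, dwell times,
    transition entropy). Includes a seeded synthetic-data generator with known
    latent structure so every stage is testable without external imaging data,
    plus delimited-text I/O and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
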