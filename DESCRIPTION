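Package: dklgp
Title: Deep Kernel Learning Gaussian Processes for Reaction Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact Gaussian process regression with a Matern-5/2 kernel
    composed with neural feature extractors (deep kernel learning) for
    predicting chemical reaction yields with calibrated uncertainty.
    Provides reaction featurization from SMILES (concatenated or summed
    Morgan fingerprints, a differential reaction fingerprint, descriptor
    concatenation, molecular graphs), a feed-forward extractor for vector
    inputs and a message-passing neural network with set2set readout for
    graphs, joint training of all kernel and network parameters by the GP
    log marginal likelihood, an evaluation protocol (repeated random and
    leave-component-out splits, RMSE/MAE/R-squared/NLPD/Spearman metrics,
    learning curves, embedding cluster summaries), and expected-improvement
    Bayesian optimization over discrete candidate pools. A synthetic
    reaction-grid generator emulating high-throughput experimentation
    datasets makes the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ChemmineR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
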