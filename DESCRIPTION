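Package: SynapticPolarity
Title: Inference of Synaptic Polarity in Signed Directed Connectomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational inference of chemical-synapse polarity
    (excitatory vs inhibitory) in directed neuronal networks. Implements
    the connectome model (CM) combining neurotransmitter and receptor
    expression with a signed wiring-rule network, the spatial connectome
    model (SCM) that learns a minimal rule matrix from known polarities by
    spatially truncated ridge regression, the generalized connectome model
    (GCM) operating on the signed network alone, and closed-form signed
    link-sign predictors (SL2, SL3, signed preferential attachment).
    Includes precision-at-rank evaluation, k-fold cross-validation,
    subsampling robustness experiments, and a planted-rule synthetic data
    generator emulating the Caenorhabditis elegans chemical connectome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
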