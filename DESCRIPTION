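Package: sparseddi
Title: Sparse Hypergraph Latent-Interaction Models for Drug-Drug
    Interaction Side Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts side effects of drug-drug interactions from a DDI
    hypergraph whose hyperedges are (drug, drug, side effect) triples.
    Drugs and side effects are embedded into nonnegative latent spaces by
    a message-passing hypergraph neural network, and a nonnegative 3-way
    tensor of latent-feature interactions scores each triple through
    n-mode tensor products.  Model sparsity is controlled by a horseshoe
    shrinkage prior (with Laplace and no-prior variants), fitted by
    maximum a posteriori gradient ascent.  Includes a synthetic hypergraph
    generator with planted latent interactions, a stratified k-fold
    cross-validation protocol with AUC/AUPR evaluation, and an
    interpretation routine mapping predicted triples back to the
    observable drug features most associated with their active latent
    interactions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
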