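Package: msinteractome
Title: Multiscale Interactome Diffusion Profiles for Drug-Disease Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous networks of drugs, diseases, proteins and a
    hierarchy of biological functions, and propagates drug and disease effects
    across them with per-node-type biased random walks with restart. The
    resulting visitation-frequency vectors (diffusion profiles) are compared to
    rank candidate treatments for a disease, extract interpretable treatment
    subgraphs, and prioritize pharmacogenes whose variation alters treatment.
    Includes classical comparison baselines (target overlap, network proximity
    with degree-matched permutation nulls, Gene Ontology semantic similarity)
    and a synthetic-network generator with planted treatment structure so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
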