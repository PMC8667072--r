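Package: NetScreen
Title: Network Propagation and Screening for Latent Disease-Gene Discovery
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies latent disease-associated genes by random walk with
    restart over a weighted protein-protein interaction network, followed by
    a three-stage screening cascade: a permutation Z-score against random
    seed sets, a maximum association score against validated disease genes,
    and a maximum function score computed as the cosine similarity of
    hypergeometric enrichment vectors. A final gene-ontology
    over-representation step characterises the putative genes. Includes a
    synthetic planted-module network generator so the whole pipeline can be
    exercised and calibrated without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, NetworkInference, GeneSetEnrichment,
    Software
RoxygenNote: 7.3.3
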