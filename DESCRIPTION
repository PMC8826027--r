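Package: netfactor
Title: Network-Constrained Construction of Sparse Predictive Models for
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds sparse, biologically structured predictive models for
    gene expression phenotype classification. Candidate protein complexes
    are discovered in a protein-protein interaction network with
    deterministic overlapping clustering algorithms (MCODE, DPClus, IPCA,
    COACH); the discovered complexes define a bipartite gene-to-complex
    factor graph that becomes the sparsity mask of a two-layer neural
    model mapping expression profiles to complex activities and on to
    phenotype classes. Includes randomly structured control models, a
    repeated stratified-split evaluation protocol with balanced accuracy,
    prevalence-weighted one-vs-rest AUC and the correlated t-test, layer
    integrated-gradients attribution of complex nodes, and a
    planted-complex synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
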