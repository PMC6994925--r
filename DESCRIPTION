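Package: lipidnet
Title: Integrated Lipidome-Transcriptome Analysis with O2PLS and
    Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for paired lipidomics and bulk
    transcriptomics studies of diet-induced peripheral neuropathy models:
    lipid identifier parsing, K-nearest-neighbour imputation,
    internal-standard normalisation, ion-mode merging and class/acyl-chain
    summarisation; differential lipid and gene analysis with
    Benjamini-Hochberg control and disease-versus-reversal overlap
    classification; a from-scratch two-way orthogonal partial least
    squares (O2PLS) model with variance partitioning, cross-validated
    component selection and top-loading candidate extraction; an
    annotation-filtered lipid-gene Pearson correlation network with
    modularity-based subnetwork detection; and a deterministic synthetic
    paired-omics generator emulating a five-group, two-timepoint
    sciatic-nerve study design for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
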