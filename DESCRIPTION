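Package: triscreen
Title: Multi-Representation Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening that combines three molecular
    representations: substructure-sentence embeddings trained with
    skip-gram negative sampling (Mol2vec-style), 2D pharmacophore-pair
    fingerprints over binned topological distances, and 3D conformer
    feature-map fingerprints. Screening-library compounds are scored
    against a panel of reference actives by per-representation similarity,
    passed through a hyper-space filter with a similarity cut-off that
    rejects both dissimilar compounds and exact duplicates of the
    references, and aggregated across representations into a ranked
    candidate list. Includes a synthetic fixture generator (reference
    panel, planted analogues, decoys, pre-training corpus) so the whole
    pipeline runs and is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
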