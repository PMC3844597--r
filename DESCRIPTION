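Package: drugsig
Title: Drug-Induced Transcriptional Signature Screening and Mechanism Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-course drug-perturbation transcriptomics in the
    rodent brain. Implements a screening pipeline for drug-responsive
    transcripts (quantile normalization, per-batch z-score standardization,
    vectorised balanced two-way ANOVA with Bonferroni and Benjamini-Hochberg
    correction, true-positive estimation over an FDR range), a composite
    gene-selection score combining per-time significance, magnitude and
    cross-time consistency of fold changes, classification of drugs by their
    expression profiles (hierarchical clustering and PCA), extraction of
    co-expressed gene networks on a minimal-spanning-tree transcriptome map
    under a walk-length metric, generic over-representation analysis, and
    model-based inference of a drug's pharmacological mechanisms from its
    expression signature via a bilinear drug-by-mechanism least-squares model.
    A synthetic-data generator with planted ground truth supports recovery
    benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
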