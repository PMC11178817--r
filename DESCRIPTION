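Package: atlasfuse
Title: Hierarchical Atlas Integration and Querying of Brain Expression and Connectivity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps heterogeneous brain transcriptomic and connectivity data onto a
    common voxel reference space through a hierarchical brain-region ontology, and
    queries the result at any anatomical level. Provides volume-of-interest (VOI)
    gene-expression queries (mean expression, region specificity, cell-type
    specificity, enrichment), ingestion and normalization of sample-based
    expression matrices (QC filtering, CPM, RPKM-to-TPM, log2(x+1), scaled robust
    sigmoid, gene matching), voxel-level structural connectome assembly from
    injection records (max-combine, hemisphere mirroring, thresholding),
    Morton-order space-filling-curve spatial indexing with metadata
    pre-aggregation, cross-species expression-connectivity correlation statistics,
    and a deterministic synthetic-fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
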