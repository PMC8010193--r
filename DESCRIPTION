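Package: vlsmap
Title: Voxel-Based Lesion-Symptom Mapping for Radiogenomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based lesion-symptom mapping (VLSM) for cohorts of binary
    tumor masks on a shared template grid, linking lesion topography to a
    binary molecular label with the quasi-exact Liebermeister test,
    Benjamini-Hochberg false discovery rate control and connected-cluster
    extraction. Includes cohort overlay maps, region-membership
    classification with contingency reporting, inter-rater kappa statistics,
    Kaplan-Meier/log-rank survival comparison, single-sample gene-set
    enrichment (ssGSEA) scoring of expression profiles with a signature-based
    tumor-purity proxy and per-gene differential expression, plus a coupled
    imaging/clinical/expression cohort simulator that provides ground truth
    for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
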