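Package: panelqc
Title: SNP Panel Selection and Quality-Control Genotyping for Inbred Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quality-control (QC) genotyping of inbred line
    collections from SNP genotype matrices. Computes per-marker
    informativeness statistics (minor allele frequency, heterogeneity,
    missing rate, polymorphic information content, coverage, mutation
    class), pairwise allele-sharing distances and identity-by-state
    similarities, complete-linkage clustering and principal coordinate
    embeddings of entries. Selects nested "broad" and "rapid" QC marker
    panels by threshold filtering, PCA + K-means marker grouping with
    proportional allocation strategies, uniform genomic spacing, and
    replicated resampling that maximises pairwise discrimination of
    entries. Verifies line identity by blind-test assignment, flags
    mislabeling and residual heterogeneity, counts off-type individuals
    per entry, and plans sampling via binomial detection power and
    Beta-posterior upper limits on the population off-type proportion.
    A seeded simulator of structured inbred panels, regenerations, and
    contamination events provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
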