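Package: phenomap
Title: Hierarchical Phecode Phenotyping and Phenome-Wide Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for phecode-based phenotyping of electronic health record
    data. Parses and validates phecode mapping files in both the prefixed
    hierarchical dialect (two-letter category prefix, three-digit root, up to
    three decimal child levels, multi-mapping, no exclude ranges) and the
    legacy numeric dialect (one-to-one mapping with per-phecode exclude
    ranges), across the ICD-9-CM, ICD-10-CM and WHO ICD-10 vocabularies.
    Translates dated person-level ICD event streams into hierarchically
    rolled-up person-by-phecode count matrices, assigns case/control status
    under a minimum distinct-date code count, applies legacy exclude-range
    control removal, and runs per-phecode logistic phenome-wide association
    scans with case-count filtering and Bonferroni thresholds. A seeded
    synthetic-data module generates grammar-valid miniature maps and simulated
    cohorts with planted genotype-phenotype effects so the full pipeline is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
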