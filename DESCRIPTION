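Package: mautopsy
Title: Cohort-Level Molecular Autopsy Analysis for Sudden Death in the Young
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-level interpretation of postmortem genetic
    testing (molecular autopsy) in sudden death in the young. Implements the
    multi-stage rare-variant filter cascade with allele-frequency thresholds,
    pathogenicity categorisation and three-tier causal interpretation,
    gene-panel versus whole-exome yield comparison, cross-sample pathogenic
    gene co-occurrence, Jaccard/Z-score genetic fingerprinting with
    hierarchical clustering, mitochondrial heteroplasmy burden and maternal
    sharing analysis, combined forensic/molecular diagnostic-yield tables,
    and exact binomial temporal-clustering tests. A seeded synthetic cohort
    generator reproduces the statistical structure the analyses assume so
    that every pipeline stage is testable without access to protected
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
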