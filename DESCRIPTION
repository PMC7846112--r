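Package: famvar
Title: Family-Based Rare-Variant Prioritization for Dominant Thrombophilia Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based discovery of rare variants under an
    autosomal-dominant, fully penetrant model: PED pedigree parsing and
    validation, recursive kinship coefficients, kinship-guided selection of
    sequencing subjects, a five-stage whole-exome filtering cascade
    (case-sharing, control-exclusion, functional class, reference-panel
    rarity, in-silico deleteriousness) with an auditable stage report,
    co-segregation checking across a fully genotyped pedigree, carrier
    screening in external cohorts with reference-panel allele-count
    aggregation, and exact small-sample Mann-Whitney comparison of plasma
    coagulation phenotypes. A gene-dropping simulator generates complete
    synthetic studies (pedigree, genotypes, annotations, plasma values) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
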