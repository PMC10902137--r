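Package: droughtscreen
Title: Germination-Stage Drought-Tolerance Screening and Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening drought-tolerant germplasm at the seed
    germination stage from osmotic-stress (PEG-6000) germination trials.
    Computes germination rate, germination energy and germination index from
    daily counts, derives drought-tolerance coefficients, membership-function
    (subordinate function) scores and their average (ASFV), classifies
    genotypes into five equal-interval tolerance grades, and screens highly
    tolerant accessions across environments. Provides descriptive statistics,
    balanced two-way ANOVA variance components and broad-sense heritability,
    trait correlations, a VanRaden kinship matrix, an EMMA-style mixed
    linear model association scan with a fixed -log10(p) threshold, per-SNP
    variance explained, and haplotype allele-group comparison. A seeded
    simulator generates germination trials and SNP genotype matrices with
    planted causal variants so the whole pipeline can be exercised and
    validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
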