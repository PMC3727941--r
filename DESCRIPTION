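Package: famexome
Title: Family-Based Exome Variant Prioritization for Recessive Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate causal variants in small nuclear families
    with an autosomal recessive phenotype, as used in exome studies of
    nonsyndromic hearing loss. Implements the per-sample filtering funnel
    (mapping quality, functional impact, population-database subtraction,
    disease-gene-panel restriction), affected-sibling intersection,
    recessive-model calling (homozygous and compound heterozygous),
    trans-phase segregation checks against parental genotypes, control-cohort
    carrier counting, and low-coverage gap auditing for orthogonal follow-up
    sequencing. Includes a seeded simulator of family exomes with planted
    causal compound-heterozygous pairs, population-database structure, decoy
    variants and depth tracks, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
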