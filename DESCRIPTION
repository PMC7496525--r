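Package: speqtl
Title: Spatial eQTL Mapping from Restriction-Fragment Chromatin Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial expression quantitative trait locus (eQTL)
    analysis anchored on Hi-C restriction fragments. Digests a reference
    genome in silico with a named restriction enzyme, maps variants to
    fragments, derives SNP-gene pairs supported by fragment-fragment
    chromatin contacts, confirms tissue-specific cis- and trans-eQTLs with
    rank-normalized linear regression under Benjamini-Hochberg control,
    scans genome-wide for distal regulators of a target gene, clusters
    phased cohort haplotypes into dosage groups and tests additive effects
    on age-at-onset phenotypes, and summarizes loss-of-function intolerance
    (pLI) of connected genes by connection distance class. Includes a
    deterministic synthetic-data generator emulating the statistical
    structure of fragment-level Hi-C, Hardy-Weinberg genotypes, per-tissue
    expression with planted allelic effects, a two-cluster haplotype cohort
    and a bimodal pLI landscape, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
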