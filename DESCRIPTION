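Package: pedrecomb
Title: Pedigree-Based Analysis of Individual Recombination Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and genetic analysis of individual autosomal
    recombination rate in pedigreed populations genotyped on SNP arrays.
    Detects meiotic crossovers in gametes transmitted from a focal parent to
    its offspring using five-member subpedigrees, builds sex-specific Kosambi
    linkage maps, characterises the broad- and fine-scale recombination
    landscape, partitions phenotypic variance in autosomal crossover count
    with REML animal models (genomic or pedigree relatedness), runs
    mixed-model genome-wide association with genomic control and an LD-aware
    multiple-testing correction, performs regional heritability scans, and
    measures haplotype sharing around associated loci. A gene-dropping
    meiosis simulator with a configurable polygenic architecture generates
    synthetic pedigrees, genotypes and gametes so that every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
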