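Package: snpvault
Title: Compressed Storage and Set-Based Management of Large-Scale SNP
    Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An embedded repository for biallelic SNP genotype data.
    Genotypes are stored as 2-bit packed vectors (one record per sample and
    panel), so one byte holds four genotypes and a megabyte holds four
    million. Named genotype sets -- pairs of a SNP selection bit vector and
    an individual selection vector -- define subsets at virtually no storage
    cost, with hierarchical provenance. Subsets can be derived from sample
    and SNP lists or from database-side filters on duplicate records,
    chromosomes, no-call rates and minor allele frequency. PLINK ped/map
    files are imported and exported losslessly; a compact "0125" genotype
    export, a generalized entity-attribute-value phenotype store, synthetic
    ped/map data generation and a scripting-friendly command line interface
    are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
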