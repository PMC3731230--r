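Package: fungwas
Title: Association Mapping of Binary Traits in Haploid Fungal Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis for haploid microbial
    populations phenotyped with replicated count assays, as used to map
    germling communication loci in wild Neurospora crassa isolates.
    Provides genotype matrix I/O and filtering (biallelism, minor allele
    frequency), aggregation and standard-deviation binarization of
    replicate fusion-frequency phenotypes, per-SNP Fisher exact
    co-inheritance tests with memoization, permutation-based expected hit
    counts and experiment-wise false discovery rates, regional linkage
    disequilibrium (r squared) profiling, and a seeded synthetic-data
    generator emulating the statistical structure of such studies so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
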