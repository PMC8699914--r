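Package: blockcall
Title: Haplotype-Block-Guided Read Merging, Genotype Re-Calling and CNV
    Detection for Low-Coverage Sequencing of Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputation support for low read-depth whole-genome sequence
    data of fully homozygous (e.g. doubled haploid) lines. Haplotype blocks
    encoding local group-wise identity-by-descent are used to pool
    sequencing reads across locally identical lines, re-call genotypes by a
    weighted consensus rule, filter markers on estimated read-depth and
    missingness, smooth local read-depth with a Nadaraya-Watson kernel
    estimator, and call copy-number variants from depth ratios relative to
    the population average. Includes a window-based block finder, a
    doubled-haploid population simulator with Poisson read sampling and
    injected copy-number events, and evaluation statistics (discordance by
    cell provenance, imputation accuracy, allele-frequency spectra, CNV
    detection metrics, GWAS region classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
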