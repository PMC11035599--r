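Package: partprs
Title: Partitioned Polygenic Scores with Gene-Set Restriction and Region Masking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of compartment-restricted polygenic
    scores from GWAS summary statistics and target-cohort genotypes:
    genome-wide, genic, intergenic and gene-set scores with strand-aware gene
    windows, greedy LD clumping, masking of a high-LD region such as the MHC,
    principal-component adjustment and standardization, covariate-adjusted
    association with continuous (white-matter tract) phenotypes under
    Bonferroni test families, per-chromosome intergenic scans, and a
    method-of-moments estimator of block-wise local heritability and local
    genetic correlation. Includes a synthetic-cohort generator with blockwise
    linkage disequilibrium so the full pipeline is testable without cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
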