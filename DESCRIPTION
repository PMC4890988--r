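Package: pathintegrate
Title: Integrative Pathway Association Analysis from GWAS and Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies disease-associated biological pathways by integrating
    case-control genotype evidence with gene expression evidence. Per-SNP
    association is scored with the Cochran-Armitage trend test, reduced to
    gene-wise p-values through LD-aware tagSNP selection (greedy r2 cover
    against a reference panel) and a minimum-p rule; differential expression
    is scored with two-sample t-tests; the two gene-level p-values are
    combined by Fisher's method, and pathway scores are assessed against a
    gene-resampling permutation null with Benjamini-Hochberg FDR control.
    Includes a synthetic-data generator with planted causal SNPs,
    differentially expressed genes and enriched pathways for end-to-end
    validation, plus readers and writers for PLINK text, VCF, BED, GMT and
    TSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
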