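Package: pathpart
Title: Partitioning Genomic Variance by Biological Pathways with Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much genomic variance is explained by the markers
    linked to a gene set (for example a KEGG pathway) using a two-variance-
    component genomic linear mixed model (GBLUP relationship matrices built
    from the set and its complement), estimated by average-information REML.
    Significance is assessed competitively against randomly sampled gene
    groups: monotone quantile-regression threshold curves for the likelihood
    ratio and the explained-variance fraction as functions of group size,
    chi-square reference selection by Kolmogorov-Smirnov distance, and
    Benjamini-Hochberg false discovery rate control. Includes readers for
    VCF, PLINK and dosage genotypes, GFF3/TSV gene annotation, GMT/TSV
    pathway maps, and a synthetic-data generator emulating dairy-cattle-style
    deregressed-proof phenotypes with reliability weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
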