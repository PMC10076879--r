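Package: methexint
Title: Integrated Differential Methylation and Expression Analysis for
    Matched Case-Control Tissue Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired case/control studies that profile
    both DNA methylation (450K-style beta-value matrices) and gene expression
    (RNA-seq count matrices) on the same tissue pairs, as in eutopic versus
    ectopic endometrium designs. Provides differential methylation calling
    (Wilcoxon rank-sum with a delta-beta effect-size gate), CpG-island and
    genomic region annotation of probes, a simplified negative-binomial Wald
    differential expression stage with median-of-ratios normalization,
    gene-level integration of methylation and expression with promoter- and
    enhancer-related differentially methylated gene classification and
    quadrant partitioning, hypergeometric over-representation analysis
    against GMT gene-set collections, 2^-ddCt qPCR relative quantification
    with normality-driven test selection, and a synthetic-data generator with
    planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    limma,
    nortest,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
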