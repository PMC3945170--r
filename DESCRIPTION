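Package: methyLink
Title: Integrated Differential Methylation and Expression Analysis with
    Context-Structured Interaction Prioritization
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for two-group Illumina-style DNA
    methylation (beta-value) and gene expression microarray studies.
    Annotates CpG probes by gene context (TSS1500, TSS200, 5'UTR, first
    exon, body, 3'UTR) and by merged CpG-island context (island, 4-kb
    shore, open sea); normalizes and filters both platforms; calls
    differential expression with an empirical-Bayes moderated t and
    differential methylation with a delta-beta rule; links differentially
    methylated CpGs to differentially expressed transcripts and classifies
    each pair by the sign of the Spearman correlation; runs context-
    stratified tests of proportions; prioritizes genes by a per-gene
    two-factor ANOVA interaction between CpG methylation status and CpG
    location under both location taxonomies; and performs generic
    hypergeometric over-representation analysis. A synthetic-data module
    generates manifests, bimodal beta-value matrices and coupled
    expression data with planted, context-structured effects and a truth
    table so every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr,
    rmarkdown
biocViews: DNAMethylation, GeneExpression, DifferentialMethylation,
    DifferentialExpression, Microarray, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
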