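Package: dremseq
Title: Dietary-Restriction Memory Analysis of Expression and Promoter Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse "cellular memory" of dietary restriction (DR)
    across ad-libitum (AL), DR, and DR-switched-back-to-AL (DR-AL) diet
    groups. Implements differential expression between unreplicated pooled
    RNA-seq libraries with a variance-stabilising square-root transform and
    Poisson Z-test, Benjamini-Hochberg correction and a fold-change filter;
    classification of DR-induced expression changes as persistent or
    transient after the diet switch, with cross-tissue intersection of
    persistent gene sets; comparative-Ct (2^-ddCt) relative quantification
    of qPCR plates; and bisulfite amplicon sequencing (BSAS) quantitation
    of single-cytosine methylation in CG and CH contexts with total and
    per-site group statistics. A synthetic-data module generates count
    tables, bisulfite amplicon reads and qPCR plates with known ground
    truth emulating the three-group study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, DifferentialExpression,
    Sequencing, Software
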