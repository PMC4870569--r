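Package: uuoSeq
Title: Differential Expression and lncRNA Genomic-Context Analysis for
    Obstructive Renal Fibrosis RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end bulk RNA-seq analysis pipeline for the unilateral
    ureteric obstruction (UUO) model of progressive renal fibrosis: gene-level
    count filtering (length, read-density and median rules), median-of-ratios
    normalization, negative-binomial Wald testing across the sham / 2-day /
    8-day contrasts with Benjamini-Hochberg correction, classification of long
    non-coding RNAs by their genomic relationship to protein-coding genes
    (intergenic, intronic, antisense, bidirectional), a +/- 100 kb cis-neighbor
    scan with expression-concordance labelling, proximity-based candidate
    selection, hypergeometric gene-set over-representation, and sample-level
    QC (classical MDS, Ward clustering). Includes a negative-binomial count
    and annotation simulator with planted ground truth for validating every
    stage.
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
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
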