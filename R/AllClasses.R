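#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

#' Pipeline configuration
#'
#' Holds every tunable threshold of the analysis in one validated object.
#' Defaults reproduce the study conditions: genes shorter than 500 bp are
#' discarded, read-density and median filters use the 25th quantile and the
#' median of the normalized distribution, differential expression is gated at
#' raw p < 0.05 (list membership) or BH FDR < 0.05 (heatmap selection) with an
#' absolute log2 fold-change cutoff of 1, cis-neighbors are scanned within
#' +/- 100 kb and proximity candidates require < 3 kb.
#'
#' @slot minGeneLength minimum exon-union gene length in bp (rule i).
#' @slot lowcountQuantile quantile of the read-density distribution (rule ii).
#' @slot applyMedianFilter whether the median-count rule (iii) is applied.
#' @slot pThreshold raw p-value significance gate.
#' @slot fdrThreshold BH-adjusted significance gate.
#' @slot log2fcCutoff absolute log2 fold-change cutoff for up/down calls.
#' @slot neighborWindow cis-neighbor scan window in bp.
#' @slot proximityCutoff candidate proximity cutoff in bp (strict less-than).
#' @slot bidirectionalTssWindow maximum TSS-to-TSS distance in bp for the
#'   divergent (bidirectional) lncRNA class.
#' @slot detectionRpkmThreshold RPKM above which a gene counts as detected
#'   (strict greater-than).
#' @slot pseudocount offset added to normalized group means before fold
#'   changes, keeping them finite.
#' @slot seed integer seed governing all stochastic stages.
#'
#' @seealso [pipelineConfig()] for the user-facing constructor.
#' @export
setClass("PipelineConfig",
  slots = c(
    minGeneLength = "numeric",
    lowcountQuantile = "numeric",
    applyMedianFilter = "logical",
    pThreshold = "numeric",
    fdrThreshold = "numeric",
    log2fcCutoff = "numeric",
    neighborWindow = "numeric",
    proximityCutoff = "numeric",
    bidirectionalTssWindow = "numeric",
    detectionRpkmThreshold = "numeric",
    pseudocount = "numeric",
    seed = "integer"
  ),
  prototype = list(
    minGeneLength = 500,
    lowcountQuantile = 0.25,
    applyMedianFilter = TRUE,
    pThreshold = 0.05,
    fdrThreshold = 0.05,
    log2fcCutoff = 1.0,
    neighborWindow = 1e5,
    proximityCutoff = 3000,
    bidirectionalTssWindow = 1000,
    detectionRpkmThreshold = 0,
    pseudocount = 0.5,
    seed = 1L
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  num <- c(
    minGeneLength = object@minGeneLength,
    pThreshold = object@pThreshold,
    fdrThreshold = object@fdrThreshold,
    log2fcCutoff = object@log2fcCutoff,
    neighborWindow = object@neighborWindow,
    proximityCutoff = object@proximityCutoff,
    bidirectionalTssWindow = object@bidirectionalTssWindow,
    detectionRpkmThreshold = object@detectionRpkmThreshold,
    pseudocount = object@pseudocount
  )
  if (any(!is.finite(num)) || any(num < 0))
    msg <- c(msg, "all thresholds must be finite and >= 0")
  q <- object@lowcountQuantile
  if (!is.finite(q) || q <= 0 || q >= 1)
    msg <- c(msg, "lowcountQuantile must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Genome annotation with gene models
#'
#' A set of strand-aware gene models: one span per gene plus its exon set,
#' with biotype resolved to protein_coding, lncRNA or other. Chromosome
#' lengths, when known, live in the seqinfo of the gene ranges and every gene
#' is validated against them.
#'
#' @slot genes a [GenomicRanges::GRanges] of gene spans, named by gene_id,
#'   with metadata columns `gene_id`, `symbol` and `biotype`.
#' @slot exons a [GenomicRanges::GRangesList] parallel to `genes` (same names)
#'   holding each gene's exons on the gene's chromosome and strand.
#'
#' @seealso [readGTF()], [writeGTF()], [GenomeAnnotation()]
#' @export
setClass("GenomeAnnotation",
  slots = c(genes = "GRanges", exons = "CompressedGRangesList")
)

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  e <- object@exons
  msg <- character()
  ids <- names(g)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "gene ids must be present and unique")
  if (!identical(names(e), ids))
    msg <- c(msg, "exons must be named identically to genes")
  if (!all(c("gene_id", "symbol", "biotype") %in% colnames(mcols(g))))
    msg <- c(msg, "genes need gene_id, symbol and biotype metadata columns")
  if (length(g)) {
    echr <- as.character(unlist(seqnames(e), use.names = FALSE))
    estr <- as.character(unlist(strand(e), use.names = FALSE))
    gchr <- rep(as.character(seqnames(g)), lengths(e))
    gstr <- rep(as.character(strand(g)), lengths(e))
    if (!all(echr == gchr) || !all(estr == gstr))
      msg <- c(msg, "every exon must share its gene's chromosome and strand")
    sl <- GenomeInfoDb::seqlengths(g)
    known <- !is.na(sl[as.character(seqnames(g))])
    if (any(known)) {
      bound <- sl[as.character(seqnames(g))][known]
      if (any(start(g)[known] < 1) || any(end(g)[known] > bound))
        msg <- c(msg, "gene spans must lie within chromosome bounds")
    }
    if (any(lengths(e) == 0))
      msg <- c(msg, "every gene needs at least one exon")
  }
  if (length(msg)) msg else TRUE
})

#' UUO count set
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the gene x sample
#' read-count matrix of the obstruction time course, the sample-to-group
#' design in `colData` (column `group`; the study uses SO, 2D and 8D), and the
#' contrast list in `metadata(x)$contrasts`. After [normalizeCounts()] the
#' median-of-ratios size factors sit in `colData(x)$sizeFactor` and the
#' normalized matrix in the `normalized` assay.
#'
#' @seealso [UUOSet()], [normalizeCounts()], [runContrasts()]
#' @export
setClass("UUOSet", contains = "SummarizedExperiment")

setValidity("UUOSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  ctr <- metadata(object)$contrasts
  if (!is.null(ctr)) {
    groups <- as.character(SummarizedExperiment::colData(object)$group)
    for (cc in ctr) {
      if (length(cc) != 2L || cc[1] == cc[2])
        msg <- c(msg, "each contrast must name two distinct groups")
      else if (!all(cc %in% groups))
        msg <- c(msg, sprintf("contrast %s vs %s names an unknown group",
                              cc[1], cc[2]))
      else if (any(table(groups)[cc] < 2L))
        msg <- c(msg, sprintf("contrast %s vs %s needs >= 2 samples per group",
                              cc[1], cc[2]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Filter cascade report
#'
#' Records how the gene filter cascade disposed of every input gene. Rules are
#' applied in order (all-zero rows, minimum length, low read density, median
#' count) and each removal is attributed to the first failing rule, so the
#' per-rule counts are disjoint and sum with the survivors to the input count.
#' The realized data-dependent thresholds (the 25th-quantile read density and
#' the median normalized count actually used) are kept for the record.
#'
#' @slot nInput number of genes entering the cascade.
#' @slot removed named integer vector with elements `zero`, `length`,
#'   `low_density`, `median`.
#' @slot surviving character vector of surviving gene ids, input order.
#' @slot thresholds named numeric vector: `density_quantile`, `median_count`.
#' @export
setClass("FilterReport",
  slots = c(
    nInput = "integer",
    removed = "integer",
    surviving = "character",
    thresholds = "numeric"
  )
)

setValidity("FilterReport", function(object) {
  need <- c("zero", "length", "low_density", "median")
  if (!identical(names(object@removed), need))
    return("removed must be named zero, length, low_density, median")
  if (object@nInput != sum(object@removed) + length(object@surviving))
    return("removed counts plus survivors must equal the input count")
  TRUE
})

#' Hierarchical clustering result
#'
#' A thin container for an agglomerative clustering of items: the merge
#' history in `stats::hclust` encoding, the merge heights, the leaf order and
#' the metric/linkage tags. Ward merges are validated to be monotone
#' non-decreasing in height.
#'
#' @slot merge integer matrix, (n-1) x 2, hclust merge encoding.
#' @slot height numeric merge heights.
#' @slot order integer leaf order.
#' @slot labels character item labels.
#' @slot metric distance metric tag.
#' @slot linkage linkage tag.
#' @export
setClass("ClusterResult",
  slots = c(
    merge = "matrix",
    height = "numeric",
    order = "integer",
    labels = "character",
    metric = "character",
    linkage = "character"
  )
)

setValidity("ClusterResult", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L)
    return("merge history must contain n - 1 steps")
  if (length(object@height) != n - 1L)
    return("one height per merge is required")
  if (is.unsorted(object@height + 1e-8 * max(1, abs(object@height))))
    return("merge heights must be non-decreasing")
  TRUE
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  gene length >=", object@minGeneLength, "bp;",
      "density quantile", object@lowcountQuantile, ";",
      "median filter", object@applyMedianFilter, "\n")
  cat("  p <", object@pThreshold, "; FDR <", object@fdrThreshold,
      "; |log2FC| >=", object@log2fcCutoff, "\n")
  cat("  neighbor window", object@neighborWindow, "bp; proximity <",
      object@proximityCutoff, "bp; divergent TSS window",
      object@bidirectionalTssWindow, "bp\n")
  cat("  detection RPKM >", object@detectionRpkmThreshold,
      "; pseudocount", object@pseudocount, "; seed", object@seed, "\n")
})

setMethod("show", "GenomeAnnotation", function(object) {
  bt <- table(factor(mcols(object@genes)$biotype,
                     levels = c("protein_coding", "lncRNA", "other")))
  cat("GenomeAnnotation with", length(object@genes), "genes (",
      bt[["protein_coding"]], "protein-coding,", bt[["lncRNA"]], "lncRNA,",
      bt[["other"]], "other ) on",
      length(GenomeInfoDb::seqlevels(object@genes)), "chromosome(s)\n")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@nInput, "genes in,",
      length(object@surviving), "surviving\n")
  cat("  removed - all-zero:", object@removed[["zero"]],
      "| length:", object@removed[["length"]],
      "| low density:", object@removed[["low_density"]],
      "| median:", object@removed[["median"]], "\n")
  cat("  realized thresholds - density 25th quantile:",
      signif(object@thresholds[["density_quantile"]], 5),
      "| median count:", signif(object@thresholds[["median_count"]], 5), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@labels), "items,",
      object@metric, "distance,", object@linkage, "linkage\n")
})
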