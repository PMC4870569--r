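#' Construct a GenomeAnnotation
#'
#' @param genes `GRanges` of gene spans with metadata columns `gene_id`,
#'   `symbol` and `biotype` (`protein_coding`, `lncRNA` or `other`).
#' @param exons `GRangesList` parallel to `genes` with each gene's exons.
#' @param chromSizes optional named vector of chromosome lengths in bp,
#'   applied to the seqinfo so spans can be validated against bounds.
#' @return a validated [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(genes, exons, chromSizes = NULL) {
  ids <- mcols(genes)$gene_id
  names(genes) <- ids
  names(exons) <- ids
  if (!is.null(chromSizes)) {
    lv <- union(GenomeInfoDb::seqlevels(genes), names(chromSizes))
    GenomeInfoDb::seqlevels(genes) <- lv
    GenomeInfoDb::seqlevels(exons) <- lv
    # out-of-bound spans are caught by the class validity check with a
    # clearer message than the GRanges trim warning
    suppressWarnings({
      GenomeInfoDb::seqlengths(genes)[names(chromSizes)] <- chromSizes
      GenomeInfoDb::seqlengths(exons)[names(chromSizes)] <- chromSizes
    })
  }
  methods::new("GenomeAnnotation", genes = genes, exons = exons)
}

#' Accessors for GenomeAnnotation
#'
#' `geneRanges` returns the gene spans, optionally restricted to one biotype;
#' `geneExons` the per-gene exon list; `geneIds` the identifiers;
#' `geneBiotype` the biotype vector named by gene id.
#'
#' @param x a [GenomeAnnotation-class].
#' @param biotype optional biotype to restrict to.
#' @return a `GRanges`, `GRangesList` or character vector respectively.
#' @name annotation-accessors
#' @export
geneRanges <- function(x, biotype = NULL) {
  stopifnot(methods::is(x, "GenomeAnnotation"))
  g <- x@genes
  if (!is.null(biotype)) g <- g[mcols(g)$biotype %in% biotype]
  g
}

#' @rdname annotation-accessors
#' @export
geneExons <- function(x) {
  stopifnot(methods::is(x, "GenomeAnnotation"))
  x@exons
}

#' @rdname annotation-accessors
#' @export
geneIds <- function(x) names(geneRanges(x))

#' @rdname annotation-accessors
#' @export
geneBiotype <- function(x) {
  g <- geneRanges(x)
  stats::setNames(mcols(g)$biotype, names(g))
}

#' Merge exon intervals into a disjoint union
#'
#' Collapses a set of (possibly overlapping or touching) exon intervals on a
#' single chromosome and strand into the minimal sorted disjoint set covering
#' the same bases. Idempotent and order-invariant.
#'
#' @param intervals a `GRanges` of exons on one chromosome and strand.
#' @return a sorted, disjoint `GRanges` covering the same bases.
#' @export
mergeExons <- function(intervals) {
  if (length(intervals) == 0L) return(intervals)
  if (length(unique(as.character(seqnames(intervals)))) != 1L)
    stop("mergeExons: intervals span more than one chromosome")
  if (length(unique(as.character(strand(intervals)))) != 1L)
    stop("mergeExons: intervals span more than one strand")
  GenomicRanges::reduce(sort(intervals))
}

#' Exon-union gene lengths
#'
#' The number of bases covered by the merged exon set of each gene: the
#' "kilobase of exon" denominator of RPKM and the length the minimum-length
#' filter rule tests.
#'
#' @param x a [GenomeAnnotation-class].
#' @param ids optional gene ids to restrict to (default: all genes).
#' @return named integer vector of exon-union lengths in bp.
#' @export
exonUnionLengths <- function(x, ids = NULL) {
  e <- geneExons(x)
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(e))
    if (length(missing))
      stop("genes missing from annotation: ", paste(missing, collapse = ", "))
    e <- e[ids]
  }
  stats::setNames(sum(width(GenomicRanges::reduce(e))), names(e))
}

#' Transcription start sites
#'
#' The first transcribed base of each gene span: the span start on the plus
#' strand, the span end on the minus strand.
#'
#' @param x a [GenomeAnnotation-class] or a `GRanges` of gene spans.
#' @return named integer vector of TSS coordinates (1-based).
#' @export
tssPositions <- function(x) {
  g <- if (methods::is(x, "GenomeAnnotation")) geneRanges(x) else x
  pos <- ifelse(as.character(strand(g)) == "-", end(g), start(g))
  stats::setNames(as.integer(pos), names(g))
}

# Edge-to-edge distance between two span sets (vectors recycled pairwise):
# 0 iff the spans overlap, otherwise the positive coordinate difference
# between the facing edges (adjacent spans have distance 1).
spanDistance <- function(start1, end1, start2, end2) {
  d <- ifelse(start2 > end1, start2 - end1,
       ifelse(start1 > end2, start1 - end2, 0L))
  as.integer(d)
}
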