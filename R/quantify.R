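#' Reads per kilobase of exon per million mapped reads
#'
#' RPKM[g, s] = counts[g, s] / ((exon_union_length_g / 1000) *
#' (column_total_s / 1e6)), where the column total is the sum of all gene
#' counts in the sample. Length normalization uses the merged exon union.
#'
#' @param counts integer gene x sample matrix or a [UUOSet-class].
#' @param annotation a [GenomeAnnotation-class] covering every gene.
#' @return numeric matrix of RPKM values, same dimnames as the counts.
#' @export
computeRPKM <- function(counts, annotation) {
  if (methods::is(counts, "UUOSet"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  len <- exonUnionLengths(annotation, ids = rownames(counts))
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("zero column total in sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts / (len / 1000), 2, tot / 1e6, "/")
}

#' Detected genes per sample and per group
#'
#' A gene is detected in a sample when its RPKM strictly exceeds the
#' threshold (default 0: at least one read). Group values are arithmetic
#' means over member samples.
#'
#' @param rpkm RPKM matrix from [computeRPKM()].
#' @param groups character vector of group labels named by sample.
#' @param threshold detection threshold on RPKM (strict greater-than).
#' @return list with `perSample` (integer) and `perGroup` (numeric means).
#' @export
countDetectedGenes <- function(rpkm, groups, threshold = 0) {
  perSample <- colSums(rpkm > threshold)
  groups <- groups[colnames(rpkm)]
  perGroup <- tapply(perSample, groups, mean)
  list(perSample = perSample, perGroup = perGroup[unique(groups)])
}

#' Drop genes with zero counts in every sample
#'
#' @param x a [UUOSet-class] or count matrix.
#' @return the input with all-zero rows removed, order preserved.
#' @export
dropZeroRows <- function(x) {
  cts <- if (methods::is(x, "UUOSet"))
    SummarizedExperiment::assay(x, "counts") else x
  keep <- rowSums(cts) > 0
  x[keep, ]
}

#' Median-of-ratios size factors
#'
#' The reference for each gene is the geometric mean of its counts across
#' samples, computed over genes positive in all samples; each sample's size
#' factor is the median over those genes of count / reference. Dividing the
#' raw counts by the size factor makes samples comparable.
#'
#' @param counts integer gene x sample matrix (zero rows already dropped).
#' @return numeric vector of positive size factors named by sample.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos))
    stop("no gene is positive in all samples; filter low-count genes first")
  logc <- log(counts[allPos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - ref)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor estimate")
  sf
}

#' Normalize a UUOSet by median-of-ratios
#'
#' Estimates size factors, stores them in `colData(x)$sizeFactor` and the
#' normalized matrix (raw / size factor, exact) in the `normalized` assay.
#'
#' @param x a [UUOSet-class].
#' @return the updated [UUOSet-class].
#' @export
normalizeCounts <- function(x) {
  cts <- SummarizedExperiment::assay(x, "counts")
  sf <- sizeFactorsMedianOfRatios(cts)
  SummarizedExperiment::colData(x)$sizeFactor <- sf
  SummarizedExperiment::assays(x)$normalized <- sweep(cts, 2, sf, "/")
  x
}

#' Size factors of a normalized UUOSet
#' @param object a [UUOSet-class] after [normalizeCounts()].
#' @return numeric vector named by sample.
#' @importFrom BiocGenerics sizeFactors
#' @export
#' @aliases sizeFactors
setMethod("sizeFactors", "UUOSet", function(object) {
  sf <- SummarizedExperiment::colData(object)$sizeFactor
  if (is.null(sf)) stop("size factors not estimated; run normalizeCounts()")
  stats::setNames(sf, colnames(object))
})

#' Raw or normalized counts of a UUOSet
#' @param object a [UUOSet-class].
#' @param normalized return counts divided by the size factors?
#' @return numeric matrix.
#' @importFrom BiocGenerics counts
#' @export
#' @aliases counts
setMethod("counts", "UUOSet", function(object, normalized = FALSE) {
  if (normalized) normalizedCounts(object)
  else SummarizedExperiment::assay(object, "counts")
})

#' Normalized counts of a UUOSet
#' @param x a [UUOSet-class] after [normalizeCounts()].
#' @return numeric matrix of normalized counts.
#' @export
normalizedCounts <- function(x) {
  a <- SummarizedExperiment::assays(x)
  if (!"normalized" %in% names(a))
    stop("no normalized assay; run normalizeCounts()")
  a$normalized
}

#' Gene filter cascade
#'
#' Applies the exclusion rules in order, attributing each removal to the
#' first failing rule: (0) genes with zero normalized counts in every sample;
#' (i) genes whose exon-union length is strictly less than `minGeneLength`;
#' (ii) genes whose average normalized reads per 100 bp is strictly below the
#' `lowcountQuantile` (default 25th) quantile of that statistic over the
#' genes entering the rule; (iii) genes whose average normalized count is
#' strictly below the median over the genes entering the rule. Thresholds are
#' recomputed on the surviving set at each step and the realized values are
#' recorded. Ties at a threshold are kept.
#'
#' @param x a [UUOSet-class] after [normalizeCounts()].
#' @param annotation a [GenomeAnnotation-class].
#' @param config a [PipelineConfig-class].
#' @return a [FilterReport-class].
#' @export
filterGenes <- function(x, annotation, config = pipelineConfig()) {
  norm <- normalizedCounts(x)
  ids <- rownames(norm)
  len <- exonUnionLengths(annotation, ids = ids)
  meanNorm <- rowMeans(norm)

  alive <- rep(TRUE, length(ids))
  removedZero <- alive & meanNorm == 0
  alive <- alive & !removedZero
  removedLen <- alive & len < config@minGeneLength
  alive <- alive & !removedLen

  density <- meanNorm / (len / 100)
  qthr <- if (any(alive))
    stats::quantile(density[alive], config@lowcountQuantile, type = 7,
                    names = FALSE) else NA_real_
  removedDens <- alive & density < qthr
  alive <- alive & !removedDens

  if (config@applyMedianFilter && any(alive)) {
    mthr <- stats::median(meanNorm[alive])
    removedMed <- alive & meanNorm < mthr
    alive <- alive & !removedMed
  } else {
    mthr <- NA_real_
    removedMed <- rep(FALSE, length(ids))
  }

  methods::new("FilterReport",
    nInput = length(ids),
    removed = c(zero = sum(removedZero), length = sum(removedLen),
                low_density = sum(removedDens), median = sum(removedMed)),
    surviving = ids[alive],
    thresholds = c(density_quantile = unname(qthr),
                   median_count = unname(mthr))
  )
}

#' Surviving gene ids of a filter report
#' @param report a [FilterReport-class].
#' @return character vector of gene ids that passed every rule.
#' @export
survivingGenes <- function(report) report@surviving

#' Filter report summary as a data.frame
#' @param report a [FilterReport-class].
#' @return one-row data.frame of counts and realized thresholds.
#' @export
filterReportTable <- function(report) {
  data.frame(
    n_input = report@nInput,
    removed_zero = report@removed[["zero"]],
    removed_length = report@removed[["length"]],
    removed_low_density = report@removed[["low_density"]],
    removed_median = report@removed[["median"]],
    n_surviving = length(report@surviving),
    density_quantile = report@thresholds[["density_quantile"]],
    median_count = report@thresholds[["median_count"]]
  )
}

#' Mate inner distance for paired-end alignment
#'
#' The expected distance between the facing ends of a read pair: the average
#' fragment size minus twice the read length; the fragment-size standard
#' deviation passes through unchanged. Negative values (overlapping mates)
#' are legal and flagged with a message.
#'
#' @param meanFragment average fragment (insert) size in bp.
#' @param sdFragment standard deviation of the fragment size in bp.
#' @param readLength read length in bp.
#' @return list with `inner` and `sd`, both in bp.
#' @export
estimateMateInnerDist <- function(meanFragment, sdFragment, readLength) {
  stopifnot(meanFragment >= 0, sdFragment >= 0, readLength >= 0)
  inner <- meanFragment - 2 * readLength
  if (inner < 0)
    message("mate inner distance is negative (", inner,
            " bp): mates overlap")
  list(inner = inner, sd = sdFragment)
}
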