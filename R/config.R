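#' Create a pipeline configuration
#'
#' All tunables of the analysis with the study's defaults. See
#' [PipelineConfig-class] for the meaning and unit of each threshold.
#'
#' @param minGeneLength minimum exon-union length in bp (default 500; genes
#'   strictly shorter are removed).
#' @param lowcountQuantile quantile of the per-gene read-density distribution
#'   below which genes are removed (default 0.25).
#' @param applyMedianFilter apply the median normalized-count rule (default
#'   TRUE).
#' @param pThreshold raw p-value gate for DE list membership (default 0.05).
#' @param fdrThreshold BH FDR gate for heatmap-style selection (default 0.05).
#' @param log2fcCutoff absolute log2 fold-change cutoff separating up/down
#'   calls from significant-subthreshold ones (default 1).
#' @param neighborWindow cis-neighbor scan window in bp (default 100000).
#' @param proximityCutoff strict upper bound in bp on lncRNA-to-neighbor
#'   distance for candidate selection (default 3000).
#' @param bidirectionalTssWindow maximum TSS-to-TSS distance in bp for the
#'   divergent-promoter (bidirectional) class (default 1000).
#' @param detectionRpkmThreshold RPKM above which a gene is called detected
#'   (default 0, strict greater-than, i.e. at least one read).
#' @param pseudocount offset on normalized group means for fold changes
#'   (default 0.5).
#' @param seed integer seed for every stochastic stage (default 1).
#' @return a validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' cfg
#' @export
pipelineConfig <- function(minGeneLength = 500,
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
                           seed = 1L) {
  methods::new("PipelineConfig",
    minGeneLength = as.numeric(minGeneLength),
    lowcountQuantile = as.numeric(lowcountQuantile),
    applyMedianFilter = isTRUE(applyMedianFilter),
    pThreshold = as.numeric(pThreshold),
    fdrThreshold = as.numeric(fdrThreshold),
    log2fcCutoff = as.numeric(log2fcCutoff),
    neighborWindow = as.numeric(neighborWindow),
    proximityCutoff = as.numeric(proximityCutoff),
    bidirectionalTssWindow = as.numeric(bidirectionalTssWindow),
    detectionRpkmThreshold = as.numeric(detectionRpkmThreshold),
    pseudocount = as.numeric(pseudocount),
    seed = as.integer(seed)
  )
}

# Deterministic sub-seed for a named stage, derived from the master seed so
# stages are reproducible independently of evaluation order.
subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
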