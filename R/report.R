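#' Classical (Torgerson) MDS of samples
#'
#' Embeds samples by classical multidimensional scaling of their Euclidean
#' distances over the most variable features (genes), the standard sample-QC
#' ordination for bulk RNA-seq. Coordinates are centered; the sign of each
#' axis is fixed so its first non-zero coordinate is positive, making the
#' embedding deterministic.
#'
#' @param mat numeric samples x genes matrix (e.g. log2 normalized counts).
#' @param k embedding dimension (default 2); must be < number of samples.
#' @param nTop number of top-variance genes used (default 500; NULL = all).
#' @return samples x k coordinate matrix.
#' @export
classicalMDS <- function(mat, k = 2, nTop = 500) {
  n <- nrow(mat)
  if (n < 3L) stop("classical MDS needs >= 3 samples")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (!is.null(nTop) && ncol(mat) > nTop) {
    v <- apply(mat, 2, stats::var)
    mat <- mat[, order(v, decreasing = TRUE)[seq_len(nTop)], drop = FALSE]
  }
  d <- stats::dist(mat)
  coord <- stats::cmdscale(d, k = k)
  coord <- sweep(coord, 2, colMeans(coord))
  for (j in seq_len(ncol(coord))) {
    nz <- which(abs(coord[, j]) > 1e-12)
    if (length(nz) && coord[nz[1], j] < 0) coord[, j] <- -coord[, j]
  }
  rownames(coord) <- rownames(mat)
  colnames(coord) <- paste0("MDS", seq_len(k))
  coord
}

#' Ward hierarchical clustering
#'
#' Agglomerative Ward clustering on Euclidean distances (`stats::hclust`,
#' method `ward.D2`), for heatmap gene/sample ordering. Heights are the
#' Ward criterion and are validated to be monotone non-decreasing.
#'
#' @param mat numeric items x features matrix; rows are clustered.
#' @return a [ClusterResult-class].
#' @export
wardCluster <- function(mat) {
  if (any(!is.finite(mat))) stop("non-finite values in clustering input")
  if (nrow(mat) < 2L) stop("clustering needs >= 2 items")
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  methods::new("ClusterResult",
    merge = hc$merge, height = hc$height, order = as.integer(hc$order),
    labels = labels, metric = "euclidean", linkage = "ward")
}

#' Leaf order of a clustering
#' @param x a [ClusterResult-class].
#' @return character vector of labels in dendrogram leaf order.
#' @export
leafOrder <- function(x) x@labels[x@order]

#' Heatmap gene selection and matrix
#'
#' Genes with BH FDR below the threshold in at least one contrast, with
#' their log2(normalized + pseudocount) expression values: the selection
#' behind FDR-gated clustering heatmaps.
#'
#' @param deTables list of DE tables from [runContrasts()].
#' @param x a normalized [UUOSet-class].
#' @param config a [PipelineConfig-class].
#' @return list with `genes` (ids) and `mat` (genes x samples log2 matrix).
#' @export
heatmapSelection <- function(deTables, x, config = pipelineConfig()) {
  sel <- unique(unlist(lapply(deTables, function(de)
    de$gene_id[de$fdr < config@fdrThreshold])))
  sel <- intersect(rownames(x), sel)
  mat <- log2(normalizedCounts(x)[sel, , drop = FALSE] + config@pseudocount)
  list(genes = sel, mat = mat)
}

#' Relative expression by the double-delta-Ct method
#'
#' Replicate Ct values are averaged (arithmetic mean of cycles), then
#' ddCt = (Ct_target,condition - Ct_reference,condition) -
#' (Ct_target,baseline - Ct_reference,baseline) and the fold change is
#' 2^(-ddCt). The reference gene (GAPDH in this study) cancels loading
#' differences; the baseline condition (sham) anchors the fold at 1.
#'
#' @param ctTargetCond,ctRefCond,ctTargetBase,ctRefBase numeric vectors of
#'   replicate Ct values (cycles) for target/reference gene in the
#'   condition/baseline.
#' @return list with `ddct` and `fold` (= 2^-ddct).
#' @export
ddctFold <- function(ctTargetCond, ctRefCond, ctTargetBase, ctRefBase) {
  stopifnot(all(c(ctTargetCond, ctRefCond, ctTargetBase, ctRefBase) > 0))
  ddct <- (mean(ctTargetCond) - mean(ctRefCond)) -
    (mean(ctTargetBase) - mean(ctRefBase))
  list(ddct = ddct, fold = 2^(-ddct))
}

#' ddCt fold changes for a qPCR Ct table
#'
#' @param ct data.frame with columns `gene`, `condition`, `ct` (one row per
#'   replicate well).
#' @param reference reference gene (e.g. "Gapdh").
#' @param baseline baseline condition (e.g. "SO").
#' @return data.frame with `gene`, `condition`, `ddct`, `fold` for every
#'   non-reference gene and non-baseline condition.
#' @export
qpcrFoldTable <- function(ct, reference, baseline) {
  stopifnot(all(c("gene", "condition", "ct") %in% colnames(ct)))
  genes <- setdiff(unique(ct$gene), reference)
  conds <- setdiff(unique(ct$condition), baseline)
  pull <- function(g, cd) ct$ct[ct$gene == g & ct$condition == cd]
  rows <- lapply(genes, function(g) do.call(rbind, lapply(conds, function(cd) {
    r <- ddctFold(pull(g, cd), pull(reference, cd),
                  pull(g, baseline), pull(reference, baseline))
    data.frame(gene = g, condition = cd, ddct = r$ddct, fold = r$fold,
               stringsAsFactors = FALSE)
  })))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano table for one contrast
#'
#' Restricted to significant genes (the volcano plots show only those), with
#' log2 fold change, -log10 p and status; the up/down cutoff is recorded in
#' `attr(x, "cutoff")`.
#'
#' @param de a contrast data.frame from [runContrasts()].
#' @param config a [PipelineConfig-class].
#' @return data.frame with `gene_id`, `log2fc`, `neg_log10_p`, `status`.
#' @export
volcanoTable <- function(de, config = pipelineConfig()) {
  keep <- de$status != "not_significant"
  out <- data.frame(gene_id = de$gene_id[keep], log2fc = de$log2fc[keep],
                    neg_log10_p = -log10(de$p[keep]),
                    status = de$status[keep], stringsAsFactors = FALSE)
  attr(out, "cutoff") <- config@log2fcCutoff
  out
}
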