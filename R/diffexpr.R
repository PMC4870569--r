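#' Method-of-moments negative-binomial dispersion
#'
#' Pooled within-group estimator on normalized counts for one gene across the
#' two groups of a contrast: alpha = max(floor, (pooled within-group variance
#' - pooled mean) / pooled mean^2), floored at 1e-8. A zero pooled mean gives
#' the floor.
#'
#' @param y numeric vector of normalized counts.
#' @param group character/factor of the same length with two levels.
#' @param floor lower bound on the estimate.
#' @return non-negative dispersion estimate.
#' @export
estimateDispersionMoM <- function(y, group, floor = 1e-8) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, all(table(group) >= 2L))
  m <- mean(y)
  if (m <= 0) return(floor)
  centered <- y - stats::ave(y, group)
  v <- sum(centered^2) / (length(y) - 2L)
  max(floor, (v - m) / m^2)
}

# Vectorized dispersion over a normalized gene x sample matrix.
dispersionMoMMatrix <- function(norm, group, floor = 1e-8) {
  group <- as.factor(group)
  m <- rowMeans(norm)
  gm <- t(apply(norm, 1, function(y) stats::ave(y, group)))
  v <- rowSums((norm - gm)^2) / (ncol(norm) - 2L)
  a <- ifelse(m <= 0, floor, pmax(floor, (v - m) / m^2))
  unname(a)
}

#' Per-gene NB Wald test for one contrast
#'
#' The log2 fold change is log2((mean_test + pseudocount) / (mean_ref +
#' pseudocount)) on normalized counts. The test statistic compares the log
#' group means under the NB variance model with shared dispersion: the
#' variance of each group mean of normalized counts is (1/n^2) * sum_j
#' (q/s_j + alpha q^2), mapped to the log scale by the delta method. The
#' statistic is referred to a t distribution with n1 + n2 - 2 degrees of
#' freedom, the small-sample reference appropriate for plug-in variances at
#' the study's replicate sizes. Degenerate variance gives p = 1.
#'
#' @param y normalized counts for one gene (vector over the two groups'
#'   samples).
#' @param sf size factors of those samples.
#' @param group group labels; `ref` and `test` name the contrast.
#' @param ref,test reference and test group labels.
#' @param alpha shared dispersion estimate for the gene.
#' @param config a [PipelineConfig-class] (pseudocount).
#' @return list with `log2fc`, `p`, `baseMeanRef`, `baseMeanTest`.
#' @export
testGene <- function(y, sf, group, ref, test, alpha,
                     config = pipelineConfig()) {
  iR <- group == ref; iT <- group == test
  stopifnot(sum(iR) >= 2L, sum(iT) >= 2L)
  ps <- config@pseudocount
  mR <- mean(y[iR]); mT <- mean(y[iT])
  qR <- mR + ps; qT <- mT + ps
  log2fc <- log2(qT / qR)
  vR <- sum(qR / sf[iR] + alpha * qR^2) / sum(iR)^2
  vT <- sum(qT / sf[iT] + alpha * qT^2) / sum(iT)^2
  vLog <- vR / qR^2 + vT / qT^2
  if (!is.finite(vLog) || vLog <= 0) return(list(
    log2fc = log2fc, p = 1, baseMeanRef = mR, baseMeanTest = mT))
  z <- log(qT / qR) / sqrt(vLog)
  df <- sum(iR) + sum(iT) - 2L
  p <- 2 * stats::pt(-abs(z), df = df)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(log2fc = log2fc, p = p, baseMeanRef = mR, baseMeanTest = mT)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (capped at 1, monotone in rank) with
#' input validation: every value must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, elementwise >= the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Volcano status of a tested gene
#'
#' Genes are `up` when significant with log2 fold change at or above the
#' cutoff, `down` when significant at or below minus the cutoff,
#' `significant_subthreshold` when significant but inside the cutoff band,
#' and `not_significant` otherwise. Significance is gated on the raw p-value
#' (`gate = "raw"`, DE-list membership) or the BH FDR (`gate = "fdr"`,
#' heatmap-style selection).
#'
#' @param log2fc,p,fdr numeric vectors (recycled to common length).
#' @param config a [PipelineConfig-class].
#' @param gate `"raw"` or `"fdr"`.
#' @return character vector of statuses.
#' @export
classifyStatus <- function(log2fc, p, fdr = p, config = pipelineConfig(),
                           gate = c("raw", "fdr")) {
  gate <- match.arg(gate)
  sig <- if (gate == "raw") p < config@pThreshold else fdr < config@fdrThreshold
  ifelse(!sig, "not_significant",
    ifelse(log2fc >= config@log2fcCutoff, "up",
      ifelse(log2fc <= -config@log2fcCutoff, "down",
             "significant_subthreshold")))
}

#' Differential expression over all contrasts
#'
#' For each contrast of the design: shared-dispersion NB Wald tests per gene
#' on the normalized counts (size factors estimated once from all samples,
#' dispersion per contrast from its two groups), BH adjustment within the
#' contrast, and volcano status labels. Deterministic given its inputs.
#'
#' @param x a [UUOSet-class] after [normalizeCounts()]; apply the filter
#'   cascade first and subset to the survivors.
#' @param config a [PipelineConfig-class].
#' @param gate significance gate passed to [classifyStatus()].
#' @return named list of data.frames (one per contrast, named
#'   `ref_vs_test`) with columns gene_id, baseMeanRef, baseMeanTest, log2fc,
#'   dispersion, p, fdr, status.
#' @export
runContrasts <- function(x, config = pipelineConfig(),
                         gate = c("raw", "fdr")) {
  gate <- match.arg(gate)
  norm <- normalizedCounts(x)
  sf <- sizeFactors(x)
  groups <- sampleGroups(x)
  ps <- config@pseudocount
  out <- list()
  for (cc in contrastList(x)) {
    ref <- cc[1]; test <- cc[2]
    sel <- groups %in% c(ref, test)
    if (sum(groups == ref) < 2L || sum(groups == test) < 2L)
      stop("contrast ", ref, " vs ", test, " needs >= 2 samples per group")
    sub <- norm[, sel, drop = FALSE]
    g <- groups[sel]
    alpha <- dispersionMoMMatrix(sub, g)
    iR <- g == ref; iT <- g == test
    mR <- rowMeans(sub[, iR, drop = FALSE])
    mT <- rowMeans(sub[, iT, drop = FALSE])
    qR <- mR + ps; qT <- mT + ps
    log2fc <- log2(qT / qR)
    sR <- sf[sel][iR]; sT <- sf[sel][iT]
    vR <- (outer(qR, 1 / sR) |> rowSums()) / sum(iR)^2 +
      alpha * qR^2 / sum(iR)
    vT <- (outer(qT, 1 / sT) |> rowSums()) / sum(iT)^2 +
      alpha * qT^2 / sum(iT)
    vLog <- vR / qR^2 + vT / qT^2
    z <- ifelse(vLog > 0, log(qT / qR) / sqrt(vLog), 0)
    df <- sum(iR) + sum(iT) - 2L
    p <- 2 * stats::pt(-abs(z), df = df)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    p[!is.finite(vLog) | vLog <= 0] <- 1
    fdr <- bhAdjust(p)
    out[[contrastName(ref, test)]] <- data.frame(
      gene_id = rownames(norm),
      baseMeanRef = unname(mR), baseMeanTest = unname(mT),
      log2fc = unname(log2fc), dispersion = alpha,
      p = unname(p), fdr = unname(fdr),
      status = classifyStatus(log2fc, p, fdr, config, gate),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Two-set Venn partition
#'
#' @param A,B character vectors of gene ids.
#' @return list with disjoint sets `only_A`, `both`, `only_B` whose union is
#'   `A` union `B`.
#' @export
vennPartition <- function(A, B) {
  A <- unique(A); B <- unique(B)
  list(only_A = setdiff(A, B), both = intersect(A, B),
       only_B = setdiff(B, A))
}

#' Significant gene ids of a DE table
#' @param de a contrast data.frame from [runContrasts()].
#' @param direction `"all"` (any status but not_significant), `"up"` or
#'   `"down"`.
#' @return character vector of gene ids.
#' @export
deGenes <- function(de, direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
    all = de$status != "not_significant",
    up = de$status == "up",
    down = de$status == "down")
  de$gene_id[keep]
}
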