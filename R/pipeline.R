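#' Run the full analysis pipeline
#'
#' Chains every stage on files: read GTF/counts/design, drop all-zero genes,
#' median-of-ratios normalization, the filter cascade, NB Wald differential
#' expression for the three contrasts, Venn partitions, lncRNA context and
#' proximity candidates, optional gene-set over-representation, MDS, Ward
#' clustering of the FDR-selected genes, and volcano tables. All outputs are
#' TSV (plus a BED6 of candidate loci) under `outDir`, with a run manifest
#' recording the configuration. Rerunning with the same inputs and config
#' reproduces every table byte for byte.
#'
#' @param gtf path to the annotation GTF.
#' @param counts path to the counts TSV.
#' @param design path to the design TSV.
#' @param outDir output directory (created).
#' @param config a [PipelineConfig-class].
#' @param gmt optional path to a GMT collection for enrichment.
#' @param chromSizes optional named chromosome lengths for GTF validation.
#' @return invisibly, a list with the in-memory results (`uset`, `report`,
#'   `deTables`, `context`, `candidates`, `mds`, ...).
#' @export
runPipeline <- function(gtf, counts, design, outDir,
                        config = pipelineConfig(), gmt = NULL,
                        chromSizes = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ann <- stage("read", readGTF(gtf, chromSizes = chromSizes))
  cts <- stage("read", readCountsTSV(counts))
  dsg <- stage("read", readDesignTSV(design, counts = cts))
  uset <- stage("read", UUOSet(cts, dsg))

  uset <- stage("quantify", {
    u <- dropZeroRows(uset)
    normalizeCounts(u)
  })
  rpkm <- stage("quantify", computeRPKM(uset, ann))
  detected <- stage("quantify",
    countDetectedGenes(rpkm, sampleGroups(uset),
                       config@detectionRpkmThreshold))
  report <- stage("quantify", filterGenes(uset, ann, config))
  kept <- uset[survivingGenes(report), ]

  writeResultTSV(data.frame(sample = colnames(uset),
                            size_factor = unname(sizeFactors(uset))),
                 file.path(outDir, "size_factors.tsv"))
  writeCountsTSV(round(normalizedCounts(uset), 4),
                 file.path(outDir, "normalized.tsv"))
  writeCountsTSV(round(rpkm, 4), file.path(outDir, "rpkm.tsv"))
  writeResultTSV(filterReportTable(report),
                 file.path(outDir, "filter_report.tsv"))
  writeResultTSV(data.frame(sample = names(detected$perSample),
                            detected = unname(detected$perSample)),
                 file.path(outDir, "detected_genes.tsv"))

  deTables <- stage("de", runContrasts(kept, config))
  for (cn in names(deTables))
    writeResultTSV(deTables[[cn]], file.path(outDir,
                                             paste0("de_", cn, ".tsv")))
  cns <- names(deTables)
  if (length(cns) >= 2L) {
    vp <- vennPartition(deGenes(deTables[[1]]), deGenes(deTables[[2]]))
    writeResultTSV(data.frame(
      partition = rep(c("only_A", "both", "only_B"), lengths(vp)),
      gene_id = unlist(vp, use.names = FALSE)),
      file.path(outDir, paste0("venn_", cns[1], "_", cns[2], ".tsv")))
  }

  ctx <- stage("lncrna", lncRNAContext(ann, deTables, config))
  cand <- stage("lncrna", selectCandidates(ann, deTables, config))
  writeResultTSV(ctx, file.path(outDir, "lncrna_context.tsv"))
  writeResultTSV(classDistribution(ctx),
                 file.path(outDir, "class_distribution.tsv"))
  writeResultTSV(cand, file.path(outDir, "candidates.tsv"))
  if (nrow(cand))
    exportBED(ann, cand$lncrna_id, file.path(outDir, "candidates.bed"),
              score = cand$max_abs_log2fc)

  enr <- NULL
  if (!is.null(gmt)) {
    sets <- stage("enrich", readGMT(gmt))
    enr <- stage("enrich", enrichDELists(deTables, sets, "up"))
    for (cn in names(enr))
      writeResultTSV(enr[[cn]],
                     file.path(outDir, paste0("enrichment_", cn, "_up.tsv")))
  }

  mds <- stage("report", {
    m <- classicalMDS(t(log2(normalizedCounts(uset) + config@pseudocount)))
    writeResultTSV(data.frame(sample = rownames(m), round(m, 6)),
                   file.path(outDir, "mds.tsv"))
    m
  })
  heat <- stage("report", heatmapSelection(deTables, kept, config))
  clust <- NULL
  if (length(heat$genes) >= 2L) {
    clust <- stage("report", wardCluster(heat$mat))
    writeLines(leafOrder(clust), file.path(outDir, "cluster_genes.txt"))
    writeResultTSV(data.frame(step = seq_along(clust@height),
                              left = clust@merge[, 1],
                              right = clust@merge[, 2],
                              height = round(clust@height, 6)),
                   file.path(outDir, "merges.tsv"))
    writeCountsTSV(round(heat$mat, 4),
                   file.path(outDir, "heatmap_matrix.tsv"))
  }
  for (cn in names(deTables))
    writeResultTSV(volcanoTable(deTables[[cn]], config),
                   file.path(outDir, paste0("volcano_", cn, ".tsv")))

  manifest <- c(
    package = as.character(utils::packageVersion("uuoSeq")),
    seed = config@seed,
    p_threshold = config@pThreshold,
    fdr_threshold = config@fdrThreshold,
    log2fc_cutoff = config@log2fcCutoff,
    min_gene_length = config@minGeneLength,
    lowcount_quantile = config@lowcountQuantile,
    neighbor_window = config@neighborWindow,
    proximity_cutoff = config@proximityCutoff,
    bidirectional_tss_window = config@bidirectionalTssWindow,
    pseudocount = config@pseudocount,
    n_genes_in = nrow(uset), n_genes_tested = nrow(kept)
  )
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(outDir, "run_manifest.tsv"))

  invisible(list(annotation = ann, uset = uset, kept = kept,
                 filterReport = report, detected = detected,
                 deTables = deTables, context = ctx, candidates = cand,
                 enrichment = enr, mds = mds, cluster = clust))
}
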