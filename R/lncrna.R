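#' Classify lncRNAs by genomic relationship to protein-coding genes
#'
#' Each lncRNA receives exactly one positional class, resolved by precedence
#' (overlap is stronger evidence than promoter proximity):
#' \describe{
#'   \item{antisense}{its span overlaps at least 1 bp of a coding gene's span
#'     on the opposite strand;}
#'   \item{intronic}{its span lies entirely within a single intron (the gap
#'     between consecutive merged exons) of a same-strand coding gene;}
#'   \item{bidirectional}{no overlap, opposite strands, divergent orientation
#'     (the two TSSs point away from each other) and TSS-to-TSS distance at
#'     most `bidirectionalTssWindow`;}
#'   \item{intergenic}{none of the above.}
#' }
#' Same-strand overlap that is not intronic falls through to intergenic and
#' is flagged in the `sense_overlap` column.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param config a [PipelineConfig-class].
#' @param ids lncRNA gene ids to classify (default: all lncRNAs).
#' @return data.frame with columns `lncrna_id`, `class`, `sense_overlap`.
#' @export
classifyLncRNA <- function(annotation, config = pipelineConfig(),
                           ids = NULL) {
  biotype <- geneBiotype(annotation)
  if (is.null(ids)) ids <- names(biotype)[biotype == "lncRNA"]
  if (any(biotype[ids] != "lncRNA"))
    stop("non-lncRNA input: ",
         paste(ids[biotype[ids] != "lncRNA"], collapse = ", "))
  lnc <- geneRanges(annotation)[ids]
  coding <- geneRanges(annotation, biotype = "protein_coding")
  n <- length(lnc)
  cls <- rep("intergenic", n)
  senseOv <- rep(FALSE, n)
  if (length(coding) == 0L || n == 0L)
    return(data.frame(lncrna_id = ids, class = cls,
                      sense_overlap = senseOv, stringsAsFactors = FALSE))

  # span overlaps, strand-blind, split into anti-/sense afterwards
  ov <- GenomicRanges::findOverlaps(lnc, coding, ignore.strand = TRUE)
  sameStrand <- as.character(strand(lnc))[S4Vectors::queryHits(ov)] ==
    as.character(strand(coding))[S4Vectors::subjectHits(ov)]
  anti <- unique(S4Vectors::queryHits(ov)[!sameStrand])
  cls[anti] <- "antisense"
  senseOv[unique(S4Vectors::queryHits(ov)[sameStrand])] <- TRUE

  # introns of coding genes: span minus merged exons
  ex <- geneExons(annotation)[names(coding)]
  introns <- GenomicRanges::psetdiff(GenomicRanges::granges(coding),
                                     GenomicRanges::reduce(ex))
  intronGR <- unlist(introns, use.names = FALSE)
  intronGene <- rep(seq_along(coding), lengths(introns))
  if (length(intronGR)) {
    ovIn <- GenomicRanges::findOverlaps(lnc, intronGR, type = "within",
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ovIn)
    sh <- S4Vectors::subjectHits(ovIn)
    same <- as.character(strand(lnc))[qh] ==
      as.character(strand(coding))[intronGene[sh]]
    hit <- unique(qh[same])
    hit <- hit[cls[hit] == "intergenic"]
    cls[hit] <- "intronic"
    senseOv[hit] <- FALSE
  }

  # divergent promoters among the remainder
  remaining <- which(cls == "intergenic" & !senseOv)
  if (length(remaining)) {
    tssL <- tssPositions(lnc)
    tssC <- tssPositions(coding)
    win <- config@bidirectionalTssWindow
    lwin <- GRanges(seqnames(lnc)[remaining],
                    IRanges(pmax(1L, tssL[remaining] - win),
                            tssL[remaining] + win))
    cpts <- GRanges(seqnames(coding), IRanges(tssC, tssC))
    hits <- GenomicRanges::findOverlaps(lwin, cpts, ignore.strand = TRUE)
    for (h in seq_along(hits)) {
      i <- remaining[S4Vectors::queryHits(hits)[h]]
      j <- S4Vectors::subjectHits(hits)[h]
      if (isBidirectionalPair(
            start(lnc)[i], end(lnc)[i], as.character(strand(lnc))[i],
            tssL[i], start(coding)[j], end(coding)[j],
            as.character(strand(coding))[j], tssC[j], win))
        cls[i] <- "bidirectional"
    }
  }
  data.frame(lncrna_id = ids, class = cls, sense_overlap = senseOv,
             stringsAsFactors = FALSE)
}

# Divergent-promoter test for one lncRNA / coding gene pair on one
# chromosome: disjoint spans, opposite strands, TSSs within `win` bp and
# pointing away from each other.
isBidirectionalPair <- function(ls, le, lstr, ltss, cs, ce, cstr, ctss, win) {
  if (lstr == cstr) return(FALSE)
  if (!(ls > ce || cs > le)) return(FALSE)     # spans overlap
  if (abs(ctss - ltss) > win) return(FALSE)
  if (lstr == "+") ctss <= ltss else ctss >= ltss
}

#' Protein-coding neighbors of lncRNAs
#'
#' All coding genes whose span lies within `window` bp (edge-to-edge; 0 when
#' the spans overlap) of each lncRNA span, with signed distance (negative =
#' upstream of the lncRNA in its strand orientation) and a side label,
#' sorted by increasing absolute distance within each lncRNA.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param config a [PipelineConfig-class] (`neighborWindow`).
#' @param ids lncRNA ids to scan (default: all lncRNAs).
#' @param window override for the scan window in bp.
#' @return data.frame with columns `lncrna_id`, `gene_id`, `distance`
#'   (signed bp), `side` (`upstream`, `downstream`, `overlapping`).
#' @export
findNeighbors <- function(annotation, config = pipelineConfig(),
                          ids = NULL, window = config@neighborWindow) {
  stopifnot(window > 0)
  biotype <- geneBiotype(annotation)
  if (is.null(ids)) ids <- names(biotype)[biotype == "lncRNA"]
  lnc <- geneRanges(annotation)[ids]
  coding <- geneRanges(annotation, biotype = "protein_coding")
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      distance = integer(), side = character(),
                      stringsAsFactors = FALSE)
  if (length(lnc) == 0L || length(coding) == 0L) return(empty)
  ext <- GRanges(seqnames(lnc),
                 IRanges(pmax(1L, start(lnc) - window), end(lnc) + window))
  hits <- GenomicRanges::findOverlaps(ext, coding, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- spanDistance(start(lnc)[qh], end(lnc)[qh],
                    start(coding)[sh], end(coding)[sh])
  keep <- d <= window
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  codingLeft <- end(coding)[sh] < start(lnc)[qh]
  lncMinus <- as.character(strand(lnc))[qh] == "-"
  upstream <- ifelse(lncMinus, !codingLeft, codingLeft)
  side <- ifelse(d == 0L, "overlapping",
                 ifelse(upstream, "upstream", "downstream"))
  signed <- ifelse(d == 0L, 0L, ifelse(upstream, -d, d))
  out <- data.frame(lncrna_id = names(lnc)[qh],
                    gene_id = names(coding)[sh],
                    distance = as.integer(signed), side = side,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$lncrna_id, ids), abs(out$distance),
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression concordance between a lncRNA and a neighbor
#'
#' `similar` when both genes are significant (raw p below the threshold) in
#' the contrast with equal fold-change signs, `opposite` when both are
#' significant with differing signs, `none` otherwise. A zero log2 fold
#' change never concords.
#'
#' @param lncLog2fc,lncP lncRNA fold change and p-value in the contrast.
#' @param nbLog2fc,nbP neighbor fold change and p-value (same contrast).
#' @param config a [PipelineConfig-class].
#' @return character vector over `{similar, opposite, none}`.
#' @export
concordance <- function(lncLog2fc, lncP, nbLog2fc, nbP,
                        config = pipelineConfig()) {
  bothSig <- lncP < config@pThreshold & nbP < config@pThreshold
  s1 <- sign(lncLog2fc); s2 <- sign(nbLog2fc)
  ifelse(bothSig & s1 != 0 & s2 != 0 & s1 == s2, "similar",
    ifelse(bothSig & s1 != 0 & s2 != 0 & s1 != s2, "opposite", "none"))
}

#' Full lncRNA genomic context
#'
#' Joins positional class, cis-neighbor scan and per-contrast concordance
#' into one tidy table (one row per lncRNA x neighbor x contrast).
#' Concordance is defined only when both genes were tested in the contrast;
#' untested pairs carry NA.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param deTables list of DE tables from [runContrasts()].
#' @param config a [PipelineConfig-class].
#' @return data.frame with columns `lncrna_id`, `class`, `sense_overlap`,
#'   `gene_id`, `distance`, `side`, `contrast`, `concordance`.
#' @export
lncRNAContext <- function(annotation, deTables, config = pipelineConfig()) {
  cls <- classifyLncRNA(annotation, config)
  nb <- findNeighbors(annotation, config)
  ctx <- merge(cls, nb, by = "lncrna_id", all.x = TRUE, sort = FALSE)
  rows <- lapply(names(deTables), function(cn) {
    de <- deTables[[cn]]
    i1 <- match(ctx$lncrna_id, de$gene_id)
    i2 <- match(ctx$gene_id, de$gene_id)
    conc <- rep(NA_character_, nrow(ctx))
    ok <- !is.na(i1) & !is.na(i2)
    conc[ok] <- concordance(de$log2fc[i1[ok]], de$p[i1[ok]],
                            de$log2fc[i2[ok]], de$p[i2[ok]], config)
    cbind(ctx, data.frame(contrast = cn, concordance = conc,
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional class distribution of a lncRNA cohort
#' @param classes data.frame from [classifyLncRNA()] or the context table.
#' @return data.frame with `class` and `n`, all four classes present.
#' @export
classDistribution <- function(classes) {
  lv <- c("intergenic", "intronic", "antisense", "bidirectional")
  u <- unique(classes[, c("lncrna_id", "class")])
  tab <- table(factor(u$class, levels = lv))
  data.frame(class = lv, n = as.integer(tab), stringsAsFactors = FALSE)
}

#' Proximity candidate lncRNAs
#'
#' lncRNAs called up or down in at least one contrast whose nearest coding
#' neighbor lies strictly closer than the proximity cutoff (3 kb by
#' default), ranked by the maximum absolute log2 fold change across
#' contrasts, ties broken by smaller distance then lexicographic id. A
#' mechanical superset of a curated candidate list: no literature filter is
#' applied.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param deTables list of DE tables from [runContrasts()].
#' @param config a [PipelineConfig-class].
#' @return data.frame with columns `lncrna_id`, `class`, `nearest_gene`,
#'   `distance`, `de_contrasts`, `max_abs_log2fc`, `n_similar`,
#'   `n_opposite`.
#' @export
selectCandidates <- function(annotation, deTables,
                             config = pipelineConfig()) {
  ctx <- lncRNAContext(annotation, deTables, config)
  empty <- data.frame(lncrna_id = character(), class = character(),
                      nearest_gene = character(), distance = integer(),
                      de_contrasts = character(), max_abs_log2fc = numeric(),
                      n_similar = integer(), n_opposite = integer(),
                      stringsAsFactors = FALSE)
  lncIds <- unique(ctx$lncrna_id)
  res <- lapply(lncIds, function(id) {
    sub <- ctx[ctx$lncrna_id == id & !is.na(ctx$gene_id), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    nearest <- sub[which.min(abs(sub$distance)), , drop = FALSE][1, ]
    if (abs(nearest$distance) >= config@proximityCutoff) return(NULL)
    deIn <- character(); maxFC <- 0
    for (cn in names(deTables)) {
      de <- deTables[[cn]]
      i <- match(id, de$gene_id)
      if (!is.na(i) && de$status[i] %in% c("up", "down")) {
        deIn <- c(deIn, cn)
        maxFC <- max(maxFC, abs(de$log2fc[i]))
      }
    }
    if (!length(deIn)) return(NULL)
    data.frame(lncrna_id = id, class = nearest$class,
               nearest_gene = nearest$gene_id,
               distance = abs(nearest$distance),
               de_contrasts = paste(deIn, collapse = ","),
               max_abs_log2fc = maxFC,
               n_similar = sum(sub$concordance == "similar", na.rm = TRUE),
               n_opposite = sum(sub$concordance == "opposite", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) return(empty)
  res <- res[order(-res$max_abs_log2fc, res$distance, res$lncrna_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export gene loci as BED6
#'
#' Writes the spans of the given genes as 6-column BED (0-based half-open at
#' the file boundary, converted by rtracklayer), scored by absolute log2
#' fold change when supplied.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param ids gene ids to export.
#' @param path output file.
#' @param score optional numeric vector parallel to `ids`.
#' @return the path, invisibly.
#' @export
exportBED <- function(annotation, ids, path, score = NULL) {
  g <- geneRanges(annotation)[ids]
  mcols(g) <- NULL
  g$name <- ids
  g$score <- if (is.null(score)) 0 else score
  rtracklayer::export(g, path, format = "BED")
  invisible(path)
}
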