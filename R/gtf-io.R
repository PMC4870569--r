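#' Read an Ensembl-dialect GTF into a GenomeAnnotation
#'
#' Parses gene and exon features, groups exons by `gene_id`, and resolves
#' biotypes (from the `gene_biotype` attribute, or a caller-supplied map) to
#' `protein_coding`, `lncRNA` or `other`. Other biotypes are retained but
#' ignored by the lncRNA stage. When a gene feature is absent for a gene id
#' the span is derived from its exons.
#'
#' @param path GTF file path.
#' @param chromSizes optional named vector of chromosome lengths in bp; when
#'   given, gene spans are validated against the bounds.
#' @param biotypeMap optional named character vector gene_id -> biotype, used
#'   when the GTF lacks `gene_biotype` attributes.
#' @return a [GenomeAnnotation-class].
#' @export
readGTF <- function(path, chromSizes = NULL, biotypeMap = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields", bad))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% colnames(mcols(gr)))
    stop("GTF records lack gene_id attributes")
  feat <- as.character(gr$type)
  ex <- gr[feat == "exon"]
  gn <- gr[feat == "gene"]
  ids <- unique(c(gn$gene_id, ex$gene_id))
  if (length(ex) == 0L) stop("GTF contains no exon features")

  exList <- GenomicRanges::split(GenomicRanges::granges(ex),
                                 factor(ex$gene_id, levels = ids))
  exList <- exList[lengths(exList) > 0L]
  ids <- ids[ids %in% names(exList)]
  exList <- exList[ids]

  spans <- unlist(range(exList))
  # prefer explicit gene features for the span where present
  gnIdx <- match(ids, gn$gene_id)
  hasGene <- !is.na(gnIdx)
  if (any(hasGene)) spans[hasGene] <- GenomicRanges::granges(gn[gnIdx[hasGene]])

  getAttr <- function(obj, idx, cols, default) {
    out <- rep(NA_character_, length(idx))
    for (cl in cols) if (cl %in% colnames(mcols(obj))) {
      v <- as.character(mcols(obj)[[cl]])[idx]
      out[is.na(out)] <- v[is.na(out)]
    }
    out[is.na(out)] <- default
    out
  }
  firstExon <- match(ids, ex$gene_id)
  biotype <- getAttr(gn, gnIdx, c("gene_biotype", "gene_type"), NA)
  fromEx <- getAttr(ex, firstExon, c("gene_biotype", "gene_type"), NA)
  biotype[is.na(biotype)] <- fromEx[is.na(biotype)]
  if (!is.null(biotypeMap)) {
    mapped <- biotypeMap[ids]
    biotype[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  biotype <- normalizeBiotype(biotype)
  symbol <- getAttr(gn, gnIdx, "gene_name", NA)
  symEx <- getAttr(ex, firstExon, "gene_name", NA)
  symbol[is.na(symbol)] <- symEx[is.na(symbol)]
  symbol[is.na(symbol)] <- ids[is.na(symbol)]

  mcols(spans) <- DataFrame(gene_id = ids, symbol = symbol, biotype = biotype)
  ann <- GenomeAnnotation(spans, exList, chromSizes = chromSizes)
  methods::validObject(ann)
  ann
}

# Map raw GTF biotype strings onto the three-way scheme used here.
normalizeBiotype <- function(x) {
  lnc <- c("lncRNA", "lincRNA", "antisense", "lnc_RNA",
           "processed_transcript", "bidirectional_promoter_lncRNA")
  out <- rep("other", length(x))
  out[x %in% "protein_coding"] <- "protein_coding"
  out[x %in% lnc] <- "lncRNA"
  out[is.na(x)] <- "other"
  out
}

#' Write a GenomeAnnotation as Ensembl-dialect GTF
#'
#' Emits one `gene` feature per gene followed by its `exon` features, ordered
#' by chromosome then start, with `gene_id`, `gene_name` and `gene_biotype`
#' attributes. Round-trips with [readGTF()].
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGTF <- function(annotation, path) {
  g <- geneRanges(annotation)
  e <- geneExons(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  if (length(g) == 0L) return(invisible(path))
  ord <- order(as.character(seqnames(g)), start(g))
  fmtAttr <- function(id, sym, bt)
    sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";', id, sym, bt)
  bt <- mcols(g)$biotype
  sym <- mcols(g)$symbol
  for (i in ord) {
    at <- fmtAttr(names(g)[i], sym[i], bt[i])
    writeLines(sprintf("%s\tuuoSeq\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(seqnames(g)[i]), start(g)[i], end(g)[i],
                       as.character(strand(g)[i]), at), con)
    ei <- e[[names(g)[i]]]
    ei <- sort(ei)
    for (j in seq_along(ei)) {
      writeLines(sprintf("%s\tuuoSeq\texon\t%d\t%d\t.\t%s\t.\t%s",
                         as.character(seqnames(ei)[j]), start(ei)[j],
                         end(ei)[j], as.character(strand(ei)[j]), at), con)
    }
  }
  invisible(path)
}
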