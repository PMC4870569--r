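# small hand-built annotation covering each positional class once
handAnnotation <- function() {
  spans <- GRanges("chr1",
    IRanges(c(500, 1000, 20000, 20100, 42000, 40000, 60000, 62000),
            c(3000, 2000, 30000, 20900, 43000, 40800, 61000, 62400)),
    strand = c("+", "+", "+", "-", "+", "-", "+", "+"))
  ids <- c("codA", "lncIntron", "codB", "lncAnti", "codC", "lncBidir",
           "codD", "lncInter")
  bt <- c("protein_coding", "lncRNA", "protein_coding", "lncRNA",
          "protein_coding", "lncRNA", "protein_coding", "lncRNA")
  mcols(spans) <- S4Vectors::DataFrame(gene_id = ids, symbol = ids,
                                       biotype = bt)
  names(spans) <- ids
  ex <- list(
    codA = IRanges(c(500, 2500), c(900, 3000)),   # intron 901..2499
    lncIntron = IRanges(1000, 2000),
    codB = IRanges(c(20000, 29000), c(20500, 30000)),
    lncAnti = IRanges(20100, 20900),              # overlaps codB exon, - strand
    codC = IRanges(42000, 43000),                 # TSS 42000 (+)
    lncBidir = IRanges(40000, 40800),             # - strand, TSS 40800
    codD = IRanges(60000, 61000),
    lncInter = IRanges(62000, 62400)
  )
  exons <- GRangesList(lapply(seq_along(ids), function(i)
    GRanges("chr1", ex[[ids[i]]], strand = as.character(strand(spans))[i])))
  names(exons) <- ids
  GenomeAnnotation(spans, exons)
}

test_that("each positional class definition is recognized", {
  ann <- handAnnotation()
  cls <- classifyLncRNA(ann)
  got <- stats::setNames(cls$class, cls$lncrna_id)
  expect_equal(unname(got["lncIntron"]), "intronic")
  expect_equal(unname(got["lncAnti"]), "antisense")
  expect_equal(unname(got["lncInter"]), "intergenic")
  # divergent pair: lncBidir TSS 40800 on -, codC TSS 42000 on +, pointing
  # away but 1200 bp apart -> outside the default 1 kb window
  expect_equal(unname(got["lncBidir"]), "intergenic")
  wide <- pipelineConfig(bidirectionalTssWindow = 2000)
  got2 <- classifyLncRNA(ann, wide)
  expect_equal(got2$class[got2$lncrna_id == "lncBidir"], "bidirectional")
  expect_error(classifyLncRNA(ann, ids = "codA"), "non-lncRNA")
})

test_that("classification agrees with the brute-force scan on random genomes", {
  total <- 0L
  for (seed in 1:10) {
    ann <- randomOracleAnnotation(nCoding = 15, nLnc = 50, seed = seed)
    cls <- classifyLncRNA(ann)
    expected <- bruteClassify(ann)
    expect_identical(stats::setNames(cls$class, cls$lncrna_id),
                     expected[cls$lncrna_id])
    # total and exclusive: one class per lncRNA
    expect_equal(nrow(cls), 50L)
    expect_equal(anyDuplicated(cls$lncrna_id), 0L)
    total <- total + nrow(cls)
  }
  expect_gte(total, 500L)
})

test_that("neighbor scans agree with the brute-force all-pairs scan", {
  for (seed in 1:6) {
    ann <- randomOracleAnnotation(nCoding = 20, nLnc = 25, seed = seed + 100)
    nb <- findNeighbors(ann)
    expected <- bruteNeighbors(ann)
    key <- function(d) {
      d <- d[order(d$lncrna_id, d$gene_id), ]
      paste(d$lncrna_id, d$gene_id, d$distance)
    }
    expect_identical(key(nb[, c("lncrna_id", "gene_id", "distance")]),
                     key(expected))
    # sorted by |distance| within each lncRNA
    for (id in unique(nb$lncrna_id)) {
      d <- abs(nb$distance[nb$lncrna_id == id])
      expect_true(all(diff(d) >= 0))
    }
    # window monotonicity
    nbSmall <- findNeighbors(ann, window = 2e4)
    expect_true(all(paste(nbSmall$lncrna_id, nbSmall$gene_id) %in%
                    paste(nb$lncrna_id, nb$gene_id)))
    expect_true(all(abs(nbSmall$distance) <= 2e4))
  }
})

test_that("neighbor distances and sides follow the window boundaries", {
  spans <- GRanges("chr1", IRanges(c(1000, 52000, 210000), c(1999, 52999, 210999)),
                   strand = c("+", "+", "+"))
  ids <- c("near", "lnc", "far")
  mcols(spans) <- S4Vectors::DataFrame(gene_id = ids, symbol = ids,
    biotype = c("protein_coding", "lncRNA", "protein_coding"))
  names(spans) <- ids
  exons <- GenomicRanges::split(spans, factor(1:3))
  names(exons) <- ids
  ann <- GenomeAnnotation(spans, exons)
  nb <- findNeighbors(ann)
  # coding gene ending 50,001 bp before the lncRNA start: included, upstream
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$gene_id, "near")
  expect_equal(nb$distance, -(52000 - 1999))
  expect_equal(nb$side, "upstream")
  # the 157 kb gene is beyond the default window
  expect_false("far" %in% nb$gene_id)
})

test_that("concordance labels follow joint significance and sign", {
  cfg <- pipelineConfig()
  # both induced, like the divergent lncRNA/Cdkn1b pair
  expect_equal(concordance(2, 0.001, 1.5, 0.002, cfg), "similar")
  # lncRNA repressed while the neighbor is induced, like the Ddr2 pair
  expect_equal(concordance(-2, 0.001, 1.5, 0.002, cfg), "opposite")
  expect_equal(concordance(2, 0.001, 1.5, 0.4, cfg), "none")
  expect_equal(concordance(0, 0.001, 1.5, 0.002, cfg), "none")
})

test_that("candidate selection enforces DE status and strict proximity", {
  ann <- handAnnotation()
  mkDE <- function(ids, lfc, p) {
    data.frame(gene_id = ids, baseMeanRef = 10, baseMeanTest = 20,
               log2fc = lfc, dispersion = 0.1, p = p, fdr = p,
               status = classifyStatus(lfc, p), stringsAsFactors = FALSE)
  }
  allIds <- geneIds(ann)
  de <- list(SO_vs_2D = mkDE(allIds,
    lfc = c(codA = 0, lncIntron = 3, codB = 2, lncAnti = -2, codC = 1.2,
            lncBidir = 2.5, codD = 1.1, lncInter = 1.4)[allIds],
    p = c(codA = 0.9, lncIntron = 0.001, codB = 0.002, lncAnti = 0.01,
          codC = 0.03, lncBidir = 0.001, codD = 0.04,
          lncInter = 0.01)[allIds]))
  cand <- selectCandidates(ann, de)
  # lncInter sits 1000 bp from codD (62000 - 61000): a candidate
  expect_true(all(c("lncIntron", "lncAnti", "lncBidir", "lncInter") %in%
                  cand$lncrna_id))
  # ranked by max |log2fc|, ties by distance then id
  expect_equal(cand$lncrna_id,
               cand$lncrna_id[order(-cand$max_abs_log2fc, cand$distance,
                                    cand$lncrna_id)])

  # non-DE lncRNA at 100 bp is not a candidate
  de2 <- de
  de2$SO_vs_2D$p[de2$SO_vs_2D$gene_id == "lncInter"] <- 0.6
  de2$SO_vs_2D$status <- classifyStatus(de2$SO_vs_2D$log2fc,
                                        de2$SO_vs_2D$p)
  expect_false("lncInter" %in% selectCandidates(ann, de2)$lncrna_id)

  # boundary: neighbor at 2999 bp qualifies, 3000 bp does not
  mkPair <- function(gap) {
    spans <- GRanges("chr1", IRanges(c(1000, 2000 + gap), c(1999, 2400 + gap)),
                     strand = "+")
    ids <- c("pc", "lnc")
    mcols(spans) <- S4Vectors::DataFrame(gene_id = ids, symbol = ids,
      biotype = c("protein_coding", "lncRNA"))
    names(spans) <- ids
    exons <- GenomicRanges::split(spans, factor(1:2))
    names(exons) <- ids
    GenomeAnnotation(spans, exons)
  }
  deP <- list(SO_vs_2D = mkDE(c("pc", "lnc"), c(1.5, 2), c(0.01, 0.01)))
  # gap g means distance = start(lnc) - end(pc) = g + 1
  expect_true("lnc" %in% selectCandidates(mkPair(2998), deP)$lncrna_id)
  expect_false("lnc" %in% selectCandidates(mkPair(2999), deP)$lncrna_id)
})

test_that("class distributions cover every lncRNA exactly once", {
  fx <- makeFixture("tiny", seed = 14)
  cls <- classifyLncRNA(fx$annotation)
  dist <- classDistribution(cls)
  expect_equal(sum(dist$n), nrow(cls))
  expect_setequal(dist$class,
                  c("intergenic", "intronic", "antisense", "bidirectional"))
})

test_that("the context table defines concordance only for tested pairs", {
  fx <- makeFixture("tiny", seed = 15)
  u <- normalizeCounts(dropZeroRows(fx$uset))
  de <- runContrasts(u)
  ctx <- lncRNAContext(fx$annotation, de)
  expect_true(all(c("lncrna_id", "class", "gene_id", "distance", "side",
                    "contrast", "concordance") %in% colnames(ctx)))
  tested <- rownames(u)
  hasNb <- !is.na(ctx$gene_id)
  defined <- !is.na(ctx$concordance)
  expect_true(all(ctx$lncrna_id[defined] %in% tested))
  expect_true(all(ctx$gene_id[defined] %in% tested))
  both <- hasNb & ctx$lncrna_id %in% tested & ctx$gene_id %in% tested
  expect_true(all(defined[both]))
})

test_that("BED export converts to 0-based half-open at the boundary", {
  ann <- handAnnotation()
  path <- withr::local_tempfile(fileext = ".bed")
  exportBED(ann, c("codA", "lncInter"), path, score = c(1, 2))
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(499, 61999))
  expect_equal(bed$V3, c(3000, 62400))
  expect_equal(bed$V4, c("codA", "lncInter"))
})
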