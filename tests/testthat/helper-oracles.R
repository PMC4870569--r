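# Independent brute-force oracles. These deliberately share no code with the
# package: scalar loops, boolean coverage arrays and exhaustive enumeration,
# so that agreement with the vectorized/interval-tree implementations is
# informative.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# per-base coverage of a set of intervals as a boolean array
bruteCoverage <- function(starts, ends, width) {
  cov <- rep(FALSE, width)
  for (i in seq_along(starts)) cov[starts[i]:ends[i]] <- TRUE
  cov
}

# step-up BH adjustment, written out longhand
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (r in m:1) {
    i <- o[r]
    running <- min(running, p[i] * m / r)
    adj[i] <- min(1, running)
  }
  adj
}

# hypergeometric upper tail by exhaustive enumeration over all n-subsets
bruteHyperEnum <- function(N, K, n, k) {
  if (k == 0) return(1)
  subsets <- utils::combn(N, n)
  memb <- seq_len(N) <= K  # first K universe elements are the set
  hits <- apply(subsets, 2, function(s) sum(memb[s]) >= k)
  mean(hits)
}

# the three-rule filter cascade, recomputed longhand on plain matrices
bruteFilterCascade <- function(norm, len, minLen = 500, q = 0.25,
                               median_rule = TRUE) {
  ids <- rownames(norm)
  alive <- ids
  alive <- alive[rowMeans(norm[alive, , drop = FALSE]) > 0]
  alive <- alive[len[alive] >= minLen]
  dens <- rowMeans(norm[alive, , drop = FALSE]) / (len[alive] / 100)
  thr <- as.numeric(stats::quantile(dens, q, type = 7))
  alive <- alive[dens >= thr]
  if (median_rule) {
    mn <- rowMeans(norm[alive, , drop = FALSE])
    alive <- alive[mn >= stats::median(mn)]
  }
  alive
}

# scalar description of an annotation for the brute-force scans
flattenAnnotation <- function(ann) {
  g <- geneRanges(ann)
  ex <- geneExons(ann)
  list(
    id = names(g),
    chrom = as.character(seqnames(g)),
    start = start(g), end = end(g),
    strand = as.character(strand(g)),
    biotype = uuoSeq::geneBiotype(ann),
    tss = ifelse(as.character(strand(g)) == "-", end(g), start(g)),
    exons = lapply(seq_along(g), function(i) {
      e <- sort(GenomicRanges::reduce(ex[[i]]))
      cbind(start(e), end(e))
    })
  )
}

# brute-force positional classifier: enumerate every coding gene per lncRNA
bruteClassify <- function(ann, tssWin = 1000) {
  fa <- flattenAnnotation(ann)
  lncIdx <- which(fa$biotype == "lncRNA")
  codIdx <- which(fa$biotype == "protein_coding")
  out <- character(length(lncIdx))
  for (a in seq_along(lncIdx)) {
    i <- lncIdx[a]
    anti <- FALSE; intronic <- FALSE; bidir <- FALSE
    for (j in codIdx) {
      if (fa$chrom[j] != fa$chrom[i]) next
      overlap <- fa$start[i] <= fa$end[j] && fa$start[j] <= fa$end[i]
      opp <- fa$strand[i] != fa$strand[j]
      if (overlap && opp) anti <- TRUE
      if (overlap && !opp) {
        exm <- fa$exons[[j]]
        if (nrow(exm) >= 2) for (r in seq_len(nrow(exm) - 1)) {
          intronS <- exm[r, 2] + 1; intronE <- exm[r + 1, 1] - 1
          if (intronS <= intronE &&
              fa$start[i] >= intronS && fa$end[i] <= intronE)
            intronic <- TRUE
        }
      }
      if (!overlap && opp && abs(fa$tss[j] - fa$tss[i]) <= tssWin) {
        divergent <- if (fa$strand[i] == "+") fa$tss[j] <= fa$tss[i]
                     else fa$tss[j] >= fa$tss[i]
        if (divergent) bidir <- TRUE
      }
    }
    out[a] <- if (anti) "antisense" else if (intronic) "intronic"
              else if (bidir) "bidirectional" else "intergenic"
  }
  stats::setNames(out, fa$id[lncIdx])
}

# brute-force all-pairs neighbor scan (edge-to-edge distance)
bruteNeighbors <- function(ann, window = 1e5) {
  fa <- flattenAnnotation(ann)
  lncIdx <- which(fa$biotype == "lncRNA")
  codIdx <- which(fa$biotype == "protein_coding")
  rows <- list()
  for (i in lncIdx) for (j in codIdx) {
    if (fa$chrom[j] != fa$chrom[i]) next
    d <- if (fa$start[j] > fa$end[i]) fa$start[j] - fa$end[i]
         else if (fa$start[i] > fa$end[j]) fa$start[i] - fa$end[j] else 0
    if (d > window) next
    left <- fa$end[j] < fa$start[i]
    upstream <- if (fa$strand[i] == "-") !left else left
    rows[[length(rows) + 1]] <- data.frame(
      lncrna_id = fa$id[i], gene_id = fa$id[j],
      distance = if (d == 0) 0L else if (upstream) -d else d,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(lncrna_id = character(),
                                       gene_id = character(),
                                       distance = integer()))
  do.call(rbind, rows)
}

# exhaustive-search greedy Ward: evaluate the SSE increase of every cluster
# pair at every step and merge the cheapest
bruteWardSets <- function(mat) {
  sse <- function(idx) {
    sub <- mat[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- lapply(seq_len(nrow(mat)), identity)
  sets <- list()
  while (length(clusters) > 1) {
    best <- NULL; bestCost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      cost <- sse(c(clusters[[a]], clusters[[b]])) -
        sse(clusters[[a]]) - sse(clusters[[b]])
      if (cost < bestCost - 1e-12) { bestCost <- cost; best <- c(a, b) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    sets[[length(sets) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  sets
}

# member sets after each merge of a ClusterResult (hclust encoding)
clusterResultSets <- function(cr) {
  merge <- cr@merge
  sets <- list()
  for (s in seq_len(nrow(merge))) {
    members <- integer()
    for (side in merge[s, ]) {
      members <- c(members,
                   if (side < 0) -side else sets[[side]])
    }
    sets[[s]] <- sort(members)
  }
  sets
}

# a random annotation exercising all positional classes, independent of the
# package's planted-geometry simulator
randomOracleAnnotation <- function(nCoding = 12, nLnc = 25, seed = 1,
                                   chromLen = 2e6, nChrom = 2) {
  set.seed(seed)
  rows <- list()
  mkExons <- function(s, e, nEx) {
    if (nEx == 1 || e - s < 400) return(cbind(s, e))
    cuts <- sort(sample(seq(s + 50, e - 50), 2 * (nEx - 1)))
    starts <- c(s, cuts[seq(2, length(cuts), 2)])
    ends <- c(cuts[seq(1, length(cuts), 2)], e)
    cbind(starts, ends)
  }
  cod <- list()
  for (i in seq_len(nCoding)) {
    chrom <- paste0("chr", sample(nChrom, 1))
    s <- sample(chromLen - 10000, 1)
    e <- s + sample(2000:8000, 1)
    cod[[i]] <- list(chrom = chrom, s = s, e = e,
                     strand = sample(c("+", "-"), 1),
                     exons = mkExons(s, e, sample(1:3, 1)))
  }
  lnc <- list()
  for (i in seq_len(nLnc)) {
    mode <- sample(c("uniform", "inside", "tss", "gap"), 1,
                   prob = c(0.3, 0.3, 0.2, 0.2))
    host <- cod[[sample(nCoding, 1)]]
    L <- sample(200:2000, 1)
    if (mode == "uniform") {
      chrom <- paste0("chr", sample(nChrom, 1))
      s <- sample(chromLen - L - 1, 1)
    } else if (mode == "inside") {
      chrom <- host$chrom
      s <- host$s + sample(0:max(1, host$e - host$s - L), 1)
    } else if (mode == "tss") {
      chrom <- host$chrom
      tss <- if (host$strand == "-") host$e else host$s
      s <- max(1, tss + sample(-2000:2000, 1))
    } else {
      chrom <- host$chrom
      s <- host$e + sample(1:4000, 1)
    }
    lnc[[i]] <- list(chrom = chrom, s = s, e = s + L - 1,
                     strand = sample(c("+", "-"), 1))
  }
  ids <- c(sprintf("cod%03d", seq_len(nCoding)),
           sprintf("lnc%03d", seq_len(nLnc)))
  spans <- GRanges(
    c(vapply(cod, `[[`, "", "chrom"), vapply(lnc, `[[`, "", "chrom")),
    IRanges(c(vapply(cod, `[[`, 0, "s"), vapply(lnc, `[[`, 0, "s")),
            c(vapply(cod, `[[`, 0, "e"), vapply(lnc, `[[`, 0, "e"))),
    strand = c(vapply(cod, `[[`, "", "strand"),
               vapply(lnc, `[[`, "", "strand")))
  mcols(spans) <- S4Vectors::DataFrame(
    gene_id = ids, symbol = ids,
    biotype = c(rep("protein_coding", nCoding), rep("lncRNA", nLnc)))
  names(spans) <- ids
  exList <- c(
    lapply(cod, function(g) GRanges(g$chrom,
                                    IRanges(g$exons[, 1], g$exons[, 2]),
                                    strand = g$strand)),
    lapply(lnc, function(g) GRanges(g$chrom, IRanges(g$s, g$e),
                                    strand = g$strand)))
  exons <- GRangesList(exList)
  names(exons) <- ids
  GenomeAnnotation(spans, exons)
}

# small random count matrix with annotation-free gene lengths, for filter
# and normalization oracles
randomCountFixture <- function(nGenes = 400, nSamples = 6, seed = 1) {
  set.seed(seed)
  counts <- matrix(rnbinom(nGenes * nSamples, mu = rlnorm(nGenes, 4, 1.3),
                           size = 5),
                   nGenes, nSamples,
                   dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                                   sprintf("s%d", seq_len(nSamples))))
  len <- stats::setNames(sample(100:6000, nGenes, replace = TRUE),
                         rownames(counts))
  list(counts = counts, len = len)
}

# wrap a length vector in a minimal single-exon annotation so the package
# filter sees the same lengths as the brute-force cascade
annotationFromLengths <- function(len) {
  ids <- names(len)
  starts <- cumsum(c(1, utils::head(len, -1) + 1000))
  spans <- GRanges("chr1", IRanges(starts, starts + len - 1), strand = "+")
  mcols(spans) <- S4Vectors::DataFrame(gene_id = ids, symbol = ids,
                                       biotype = "protein_coding")
  names(spans) <- ids
  exons <- GenomicRanges::split(spans, factor(seq_along(spans)))
  names(exons) <- ids
  GenomeAnnotation(spans, exons)
}
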