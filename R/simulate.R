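#' Simulation parameters
#'
#' Parameters of the synthetic genome and count generator. The defaults
#' emulate the study conditions: a cohort of 4 sham-operated, 3 two-day and 3
#' eight-day samples, ~2000 genes of which 40 are lncRNAs planted in the four
#' positional classes, log-normal baseline expression, negative-binomial
#' overdispersion typical of bulk tissue replicates, and symmetric up/down
#' log2 effects between 1 and 3.
#'
#' Coding genes are laid out on a slot grid with at least twice the
#' cis-neighbor window between consecutive genes, so the only coding gene
#' within scan range of a planted lncRNA is its intended host/partner.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLength chromosome length in bp.
#' @param nCodingGenes number of protein-coding genes.
#' @param nLncRNA named integer vector: lncRNAs per positional class
#'   (`intergenic`, `intronic`, `antisense`, `bidirectional`).
#' @param groups named integer vector of samples per group; the first name is
#'   the reference (sham) group.
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the per-gene
#'   baseline mean q_g.
#' @param dispersionMeanlog,dispersionSdlog log-normal parameters of the
#'   per-gene NB dispersion alpha_g (variance = mu + alpha mu^2).
#' @param alphaFixed if non-NULL, a single dispersion used for every gene
#'   (0 gives Poisson counts).
#' @param fractionDE probability a coding gene carries an effect in a ligated
#'   group.
#' @param lncFractionDE probability a planted lncRNA carries an effect in a
#'   ligated group.
#' @param effectRange range of |log2 effect| (uniform draw).
#' @param sizeFactorRange range of true per-sample size factors (uniform).
#' @param similarFraction fraction of DE lncRNAs whose planted effect shares
#'   the sign of their partner coding gene's (the rest oppose it).
#' @param intergenicNearFraction fraction of intergenic lncRNAs placed at
#'   `nearDistance` from their partner (the rest at `farDistance`).
#' @param nearDistance,farDistance intergenic lncRNA-to-partner distances, bp.
#' @param codingLength,codingExonLength,lncLength gene geometry in bp; coding
#'   genes get two `codingExonLength` exons flanking one intron.
#' @param neighborWindow spacing guarantee between unrelated coding genes, bp.
#' @param seed master seed; all stages draw from named substreams of it.
#' @return a validated parameter list of class `SimulationParams`.
#' @export
simulationParams <- function(nChromosomes = 4L,
                             chromLength = 1.2e8,
                             nCodingGenes = 1960L,
                             nLncRNA = c(intergenic = 10L, intronic = 10L,
                                         antisense = 10L, bidirectional = 10L),
                             groups = c(SO = 4L, "2D" = 3L, "8D" = 3L),
                             baselineMeanlog = log(100),
                             baselineSdlog = 1,
                             dispersionMeanlog = log(0.08),
                             dispersionSdlog = 0.4,
                             alphaFixed = NULL,
                             fractionDE = 0.1,
                             lncFractionDE = 0.6,
                             effectRange = c(1, 3),
                             sizeFactorRange = c(0.7, 1.4),
                             similarFraction = 0.5,
                             intergenicNearFraction = 0.5,
                             nearDistance = 2000L,
                             farDistance = 50000L,
                             codingLength = 5000L,
                             codingExonLength = 1000L,
                             lncLength = 800L,
                             neighborWindow = 1e5,
                             seed = 1L) {
  p <- list(nChromosomes = as.integer(nChromosomes),
            chromLength = chromLength,
            nCodingGenes = as.integer(nCodingGenes),
            nLncRNA = nLncRNA, groups = groups,
            baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
            dispersionMeanlog = dispersionMeanlog,
            dispersionSdlog = dispersionSdlog, alphaFixed = alphaFixed,
            fractionDE = fractionDE, lncFractionDE = lncFractionDE,
            effectRange = effectRange, sizeFactorRange = sizeFactorRange,
            similarFraction = similarFraction,
            intergenicNearFraction = intergenicNearFraction,
            nearDistance = as.integer(nearDistance),
            farDistance = as.integer(farDistance),
            codingLength = as.integer(codingLength),
            codingExonLength = as.integer(codingExonLength),
            lncLength = as.integer(lncLength),
            neighborWindow = neighborWindow,
            seed = as.integer(seed))
  stopifnot(
    p$nChromosomes >= 1L, p$nCodingGenes >= 0L,
    all(p$nLncRNA >= 0L),
    all(names(p$nLncRNA) %in%
          c("intergenic", "intronic", "antisense", "bidirectional")),
    all(p$groups >= 2L),
    all(p$effectRange >= 0), all(p$sizeFactorRange > 0),
    p$fractionDE >= 0, p$fractionDE <= 1,
    p$lncFractionDE >= 0, p$lncFractionDE <= 1,
    p$similarFraction >= 0, p$similarFraction <= 1,
    p$codingLength > 2L * p$codingExonLength + p$lncLength + 300L
  )
  class(p) <- "SimulationParams"
  p
}

#' Simulate a genome annotation with planted lncRNA classes
#'
#' Places `nCodingGenes` two-exon protein-coding genes on a slot grid (at
#' least twice the neighbor window apart edge-to-edge) and attaches each
#' requested lncRNA to a distinct host coding gene so that it satisfies the
#' geometric definition of its planted class: inside the host intron on the
#' same strand (intronic), overlapping the host span on the opposite strand
#' (antisense), divergent with TSS-to-TSS distance of at most 1 kb
#' (bidirectional), or downstream of the host at a controlled gap
#' (intergenic).
#'
#' @param params a [simulationParams()] list.
#' @return list with `annotation` (a [GenomeAnnotation-class]) and
#'   `truth` (data.frame: lncrna_id, class, partner, distance).
#' @export
simulateAnnotation <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(subSeed(params$seed, "annotation"))
  nc <- params$nCodingGenes
  nl <- sum(params$nLncRNA)
  if (nl > nc)
    stop("capacity error: need at least one coding host per lncRNA (",
         nl, " lncRNAs, ", nc, " coding genes)")
  W <- params$codingLength + 2 * params$neighborWindow + 2000
  perChrom <- floor(params$chromLength / W)
  if (perChrom < 1L || nc > perChrom * params$nChromosomes)
    stop("capacity error: ", nc, " coding genes do not fit ",
         params$nChromosomes, " chromosome(s) of ", params$chromLength,
         " bp at ", W, " bp per slot")
  L <- params$codingLength
  EX <- params$codingExonLength
  idx <- seq_len(nc) - 1L
  chrom <- paste0("chr", idx %/% perChrom + 1L)
  slot <- idx %% perChrom
  s <- as.integer(slot * W + params$neighborWindow + 1)
  e <- s + L - 1L
  strandC <- sample(c("+", "-"), nc, replace = TRUE)
  cid <- sprintf("PCG%04d", seq_len(nc))

  codingSpans <- GRanges(chrom, IRanges(s, e), strand = strandC)
  exGR <- GRanges(rep(chrom, each = 2L),
                  IRanges(as.vector(rbind(s, e - EX + 1L)),
                          as.vector(rbind(s + EX - 1L, e))),
                  strand = rep(strandC, each = 2L))
  codingExons <- GenomicRanges::split(exGR,
                                      factor(rep(seq_len(nc), each = 2L)))
  names(codingExons) <- NULL

  classes <- rep(names(params$nLncRNA), params$nLncRNA)
  hosts <- if (nl > 0L) sample(nc, nl) else integer()
  LL <- params$lncLength
  lncChrom <- character(nl); lncStart <- integer(nl); lncEnd <- integer(nl)
  lncStrand <- character(nl); dist <- integer(nl)
  opp <- function(x) ifelse(x == "+", "-", "+")
  nInter <- sum(classes == "intergenic")
  nearFlag <- rep(FALSE, nl)
  if (nInter > 0L) {
    nNear <- round(params$intergenicNearFraction * nInter)
    nearFlag[which(classes == "intergenic")[seq_len(nNear)]] <- TRUE
  }
  for (k in seq_len(nl)) {
    h <- hosts[k]
    lncChrom[k] <- chrom[h]
    cls <- classes[k]
    if (cls == "intronic") {
      lncStart[k] <- s[h] + EX + 100L
      lncEnd[k] <- lncStart[k] + LL - 1L
      lncStrand[k] <- strandC[h]
      dist[k] <- 0L
    } else if (cls == "antisense") {
      lncStart[k] <- s[h] + EX + 500L
      lncEnd[k] <- lncStart[k] + LL - 1L
      lncStrand[k] <- opp(strandC[h])
      dist[k] <- 0L
    } else if (cls == "bidirectional") {
      gap <- 101L
      if (strandC[h] == "+") {
        lncEnd[k] <- s[h] - gap
        lncStart[k] <- lncEnd[k] - LL + 1L
        lncStrand[k] <- "-"
      } else {
        lncStart[k] <- e[h] + gap
        lncEnd[k] <- lncStart[k] + LL - 1L
        lncStrand[k] <- "+"
      }
      dist[k] <- gap
    } else { # intergenic, downstream of host on the same strand
      d <- if (nearFlag[k]) params$nearDistance else params$farDistance
      lncStart[k] <- e[h] + d
      lncEnd[k] <- lncStart[k] + LL - 1L
      lncStrand[k] <- strandC[h]
      dist[k] <- d
    }
  }
  lid <- sprintf("LNC%04d", seq_len(nl))
  if (nl > 0L) {
    lncSpans <- GRanges(lncChrom, IRanges(lncStart, lncEnd),
                        strand = lncStrand)
    lncExons <- GenomicRanges::split(lncSpans, factor(seq_len(nl)))
    names(lncExons) <- NULL
    spans <- c(codingSpans, lncSpans)
    exons <- c(codingExons, lncExons)
    ids <- c(cid, lid)
    biotype <- c(rep("protein_coding", nc), rep("lncRNA", nl))
  } else {
    spans <- codingSpans; exons <- codingExons
    ids <- cid; biotype <- rep("protein_coding", nc)
  }
  mcols(spans) <- DataFrame(gene_id = ids, symbol = ids, biotype = biotype)
  names(spans) <- ids
  names(exons) <- ids
  ord <- order(as.character(seqnames(spans)), start(spans))
  chromSizes <- stats::setNames(rep(params$chromLength, params$nChromosomes),
                                paste0("chr", seq_len(params$nChromosomes)))
  ann <- GenomeAnnotation(spans[ord], exons[ord], chromSizes = chromSizes)
  methods::validObject(ann)
  truth <- data.frame(lncrna_id = lid, class = classes,
                      partner = cid[hosts], distance = dist,
                      stringsAsFactors = FALSE)
  list(annotation = ann, truth = truth)
}

#' Simulate negative-binomial counts with planted effects
#'
#' Draws counts per gene g and sample j from NB with mean
#' mu_gj = s_j * q_g * 2^(delta_g(group_j)) and variance mu + alpha_g mu^2,
#' where delta is zero in the reference group. Coding genes are declared DE
#' in a ligated group with probability `fractionDE`; planted lncRNAs with
#' probability `lncFractionDE`, in which case their partner coding gene is
#' forced DE in the same group with a sign that agrees (probability
#' `similarFraction`) or opposes.
#'
#' @param annotation a [GenomeAnnotation-class] from [simulateAnnotation()].
#' @param design data.frame with `sample` and `group` columns.
#' @param params a [simulationParams()] list.
#' @param lncTruth the placement truth from [simulateAnnotation()]; omit for
#'   a purely coding simulation.
#' @return list with `uset` (a [UUOSet-class]) and `truth` (list of
#'   data.frames: `genes` with q, alpha, per-group deltas and per-contrast
#'   betas; `samples` with true size factors; `lncrna` with planted
#'   concordance relations).
#' @export
simulateCounts <- function(annotation, design, params, lncTruth = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(subSeed(params$seed, "counts"))
  ids <- geneIds(annotation)
  ng <- length(ids)
  ns <- nrow(design)
  groups <- as.character(design$group)
  refGroup <- names(params$groups)[1]
  if (!refGroup %in% groups) refGroup <- groups[1]
  altGroups <- setdiff(unique(groups), refGroup)

  q <- stats::rlnorm(ng, params$baselineMeanlog, params$baselineSdlog)
  alpha <- if (!is.null(params$alphaFixed)) rep(params$alphaFixed, ng)
           else stats::rlnorm(ng, params$dispersionMeanlog,
                              params$dispersionSdlog)
  sf <- stats::runif(ns, params$sizeFactorRange[1], params$sizeFactorRange[2])

  biotype <- geneBiotype(annotation)
  delta <- matrix(0, ng, length(altGroups),
                  dimnames = list(ids, altGroups))
  drawEffect <- function(n) {
    stats::runif(n, params$effectRange[1], params$effectRange[2]) *
      sample(c(-1, 1), n, replace = TRUE)
  }
  isCoding <- biotype[ids] == "protein_coding"
  for (g in altGroups) {
    de <- isCoding & stats::runif(ng) < params$fractionDE
    delta[de, g] <- drawEffect(sum(de))
  }

  lncRel <- NULL
  if (!is.null(lncTruth) && nrow(lncTruth) > 0L) {
    rel <- lncTruth
    rel$de_group <- NA_character_
    rel$lnc_beta <- 0
    rel$partner_beta <- 0
    rel$relation <- "none"
    for (k in seq_len(nrow(rel))) {
      lnc <- rel$lncrna_id[k]; pc <- rel$partner[k]
      for (g in altGroups) {
        if (stats::runif(1) < params$lncFractionDE) {
          b <- drawEffect(1L)
          similar <- stats::runif(1) < params$similarFraction
          pb <- abs(drawEffect(1L)) * sign(b) * (if (similar) 1 else -1)
          delta[lnc, g] <- b
          delta[pc, g] <- pb
          rel$de_group[k] <- g
          rel$lnc_beta[k] <- b
          rel$partner_beta[k] <- pb
          rel$relation[k] <- if (similar) "similar" else "opposite"
        }
      }
    }
    lncRel <- rel
  }

  deltaAll <- cbind(delta,
                    matrix(0, ng, 1, dimnames = list(ids, refGroup)))
  mu <- outer(q, sf) * 2^deltaAll[, groups, drop = FALSE]
  counts <- matrix(0L, ng, ns, dimnames = list(ids, design$sample))
  for (j in seq_len(ns)) {
    counts[, j] <- if (all(alpha == 0)) stats::rpois(ng, mu[, j])
                   else as.integer(stats::rnbinom(ng, mu = mu[, j],
                                                  size = 1 / pmax(alpha, 1e-12)))
  }

  ctr <- if (all(c("SO", "2D", "8D") %in% groups))
    list(c("SO", "2D"), c("SO", "8D"), c("2D", "8D"))
  else utils::combn(unique(groups), 2, simplify = FALSE)
  betas <- sapply(ctr, function(cc)
    deltaAll[, cc[2]] - deltaAll[, cc[1]])
  colnames(betas) <- vapply(ctr, function(cc) contrastName(cc[1], cc[2]), "")

  geneTruth <- data.frame(gene_id = ids, biotype = unname(biotype[ids]),
                          q = q, alpha = alpha,
                          stringsAsFactors = FALSE)
  for (g in altGroups) geneTruth[[paste0("delta_", g)]] <- delta[, g]
  for (cn in colnames(betas)) geneTruth[[paste0("beta_", cn)]] <- betas[, cn]

  uset <- UUOSet(counts, design, contrasts = ctr)
  truth <- list(
    genes = geneTruth,
    samples = data.frame(sample = design$sample, group = groups,
                         size_factor = sf, stringsAsFactors = FALSE),
    lncrna = lncRel
  )
  list(uset = uset, truth = truth)
}

#' Expand a group size vector into a design table
#' @param groups named integer vector of samples per group.
#' @return data.frame with `sample` and `group` columns.
#' @export
designFromGroups <- function(groups) {
  data.frame(
    sample = unlist(lapply(names(groups), function(g)
      paste0(g, "_", seq_len(groups[[g]])))),
    group = rep(names(groups), unname(groups)),
    stringsAsFactors = FALSE
  )
}

contrastName <- function(ref, test) paste0(ref, "_vs_", test)

#' Materialize a named simulation scenario on disk
#'
#' Three scenarios: `"tiny"` (32 genes, 6 samples; loads in well under a
#' second), `"default"` (2000 genes of which 40 are planted lncRNAs, 4 sham +
#' 3 + 3 ligated samples — the study's replicate structure) and `"null"`
#' (the default geometry with every effect zero, for type-I error suites).
#' Writes `annotation.gtf`, `counts.tsv`, `design.tsv` and the truth tables,
#' and returns the in-memory objects.
#'
#' @param name scenario id: `"tiny"`, `"default"` or `"null"`.
#' @param dir output directory (created if needed); NULL skips writing.
#' @param seed master seed.
#' @return list with `annotation`, `uset`, `truth`, `params` and `dir`.
#' @export
makeFixture <- function(name = c("tiny", "default", "null"), dir = NULL,
                        seed = 1L) {
  name <- match.arg(name)
  params <- switch(name,
    tiny = simulationParams(
      nChromosomes = 2L, chromLength = 3e6, nCodingGenes = 24L,
      nLncRNA = c(intergenic = 2L, intronic = 2L, antisense = 2L,
                  bidirectional = 2L),
      groups = c(SO = 2L, "2D" = 2L, "8D" = 2L), seed = seed),
    default = simulationParams(seed = seed),
    null = simulationParams(fractionDE = 0, lncFractionDE = 0, seed = seed)
  )
  annSim <- simulateAnnotation(params)
  design <- designFromGroups(params$groups)
  cntSim <- simulateCounts(annSim$annotation, design, params,
                           lncTruth = annSim$truth)
  out <- list(annotation = annSim$annotation, uset = cntSim$uset,
              truth = cntSim$truth, placement = annSim$truth,
              params = params, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGTF(annSim$annotation, file.path(dir, "annotation.gtf"))
    writeCountsTSV(SummarizedExperiment::assay(cntSim$uset, "counts"),
                   file.path(dir, "counts.tsv"))
    writeDesignTSV(design, file.path(dir, "design.tsv"))
    writeResultTSV(cntSim$truth$genes, file.path(dir, "truth_genes.tsv"))
    writeResultTSV(cntSim$truth$samples, file.path(dir, "truth_samples.tsv"))
    if (!is.null(cntSim$truth$lncrna))
      writeResultTSV(cntSim$truth$lncrna, file.path(dir, "truth_lncrna.tsv"))
  }
  out
}
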