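test_that("classical MDS reproduces planted geometries", {
  # three mutually equidistant samples embed as an equilateral triangle
  tri <- diag(3)
  rownames(tri) <- paste0("s", 1:3)
  xy <- classicalMDS(tri, k = 2, nTop = NULL)
  d <- as.matrix(dist(xy))
  off <- d[upper.tri(d)]
  expect_lt(max(off) - min(off), 1e-9)

  # exact 2-D points are re-embedded with their original distances
  set.seed(21)
  pts <- cbind(runif(6, -3, 3), runif(6, -3, 3))
  rownames(pts) <- paste0("s", 1:6)
  emb <- classicalMDS(pts, k = 2, nTop = NULL)
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(pts)), tolerance = 1e-6)

  # a duplicated sample lands on identical coordinates
  dup <- rbind(pts, s7 = pts[1, ])
  emb2 <- classicalMDS(dup, k = 2, nTop = NULL)
  expect_equal(unname(emb2["s7", ]), unname(emb2["s1", ]), tolerance = 1e-9)

  # deterministic sign: first non-zero coordinate per axis is positive
  expect_true(all(apply(emb, 2, function(v) v[which(abs(v) > 1e-12)[1]] > 0)))

  expect_error(classicalMDS(tri, k = 3), "smaller")
  expect_error(classicalMDS(tri[1:2, ], k = 1), ">= 3")
})

test_that("Ward clustering matches exhaustive-search Ward on small inputs", {
  set.seed(22)
  for (i in 1:5) {
    n <- sample(5:6, 1)
    mat <- matrix(rnorm(n * 3), n, 3)
    rownames(mat) <- paste0("it", seq_len(n))
    cr <- wardCluster(mat)
    expect_identical(clusterResultSets(cr), bruteWardSets(mat))
    expect_true(all(diff(cr@height) >= -1e-10))
  }
})

test_that("identical items merge first at height zero", {
  mat <- rbind(a = c(1, 1), b = c(5, 2), c = c(1, 1), d = c(9, 9))
  cr <- wardCluster(mat)
  expect_equal(cr@height[1], 0)
  expect_equal(clusterResultSets(cr)[[1]], c(1, 3))
  expect_error(wardCluster(rbind(c(1, NaN), c(2, 3))), "non-finite")
})

test_that("permuting the items yields an isomorphic Ward tree", {
  set.seed(23)
  mat <- matrix(rnorm(18), 6, 3)
  rownames(mat) <- paste0("it", 1:6)
  perm <- sample(6)
  cr1 <- wardCluster(mat)
  cr2 <- wardCluster(mat[perm, ])
  sets1 <- lapply(clusterResultSets(cr1),
                  function(s) sort(rownames(mat)[s]))
  sets2 <- lapply(clusterResultSets(cr2),
                  function(s) sort(rownames(mat)[perm][s]))
  expect_setequal(sapply(sets1, paste, collapse = ","),
                  sapply(sets2, paste, collapse = ","))
  expect_equal(sort(cr1@height), sort(cr2@height), tolerance = 1e-10)
})

test_that("heatmap selection applies the FDR-in-any-contrast rule", {
  fx <- makeFixture("default", seed = 24)
  u <- normalizeCounts(dropZeroRows(fx$uset))
  de <- runContrasts(u)
  sel <- heatmapSelection(de, u)
  expected <- unique(unlist(lapply(de, function(d) d$gene_id[d$fdr < 0.05])))
  expect_setequal(sel$genes, expected)
  expect_gt(length(sel$genes), 0)
  expect_equal(rownames(sel$mat), sel$genes)
  expect_equal(sel$mat, log2(normalizedCounts(u)[sel$genes, , drop = FALSE]
                             + 0.5))

  mkDE <- function(fdr) data.frame(gene_id = "g", baseMeanRef = 1,
    baseMeanTest = 1, log2fc = 0, dispersion = 0.1, p = fdr, fdr = fdr,
    status = "not_significant", stringsAsFactors = FALSE)
  g1 <- heatmapSelection(list(a = mkDE(0.04), b = mkDE(0.8)), u)
  expect_equal(g1$genes, character(0))  # "g" is not in the matrix
  expect_true("g" %in% unlist(lapply(list(a = mkDE(0.04)), function(d)
    d$gene_id[d$fdr < 0.05])))
  g2 <- unlist(lapply(list(a = mkDE(0.06), b = mkDE(0.6)), function(d)
    d$gene_id[d$fdr < 0.05]))
  expect_length(g2, 0)
})

test_that("ddCt folds follow their closed forms and multiply", {
  expect_equal(ddctFold(20, 18, 20, 18)$fold, 1)
  expect_equal(ddctFold(19, 18, 20, 18)$fold, 2)   # one cycle earlier
  r <- ddctFold(22, 18, 20, 18)                    # ddCt = +2
  expect_equal(r$ddct, 2)
  expect_equal(r$fold, 0.25)
  # replicates are averaged before differencing
  expect_equal(ddctFold(c(19, 21), c(18, 18), c(20, 20), c(18, 18))$fold, 1)
  # multiplicative in ddCt
  fold <- function(d) 2^(-d)
  for (a in c(-2, 0.5, 1)) for (b in c(-1, 0.25))
    expect_equal(fold(a + b), fold(a) * fold(b))
  expect_error(ddctFold(-1, 18, 20, 18), "> 0")
})

test_that("qPCR tables produce one fold per gene and condition", {
  ct <- rbind(
    data.frame(gene = "Gapdh", condition = rep(c("SO", "2D"), each = 3),
               ct = c(18, 18.1, 17.9, 18, 18, 18)),
    data.frame(gene = "Sox9", condition = rep(c("SO", "2D"), each = 3),
               ct = c(26, 26, 26, 23, 23, 23)))
  folds <- qpcrFoldTable(ct, reference = "Gapdh", baseline = "SO")
  expect_equal(nrow(folds), 1L)
  expect_equal(folds$gene, "Sox9")
  expect_equal(folds$fold, 2^(3), tolerance = 0.02)
})

test_that("volcano tables carry only significant genes with correct columns", {
  cfg <- pipelineConfig()
  de <- data.frame(
    gene_id = c("sox9like", "flat", "blue"),
    baseMeanRef = c(10, 50, 20), baseMeanTest = c(500, 52, 30),
    log2fc = c(5.785, 0.05, 0.919),
    dispersion = 0.1,
    p = c(6.49e-35, 0.8, 0.029), fdr = c(1e-30, 0.9, 0.04),
    stringsAsFactors = FALSE)
  de$status <- classifyStatus(de$log2fc, de$p, de$fdr, cfg)
  vt <- volcanoTable(de, cfg)
  expect_setequal(vt$gene_id, c("sox9like", "blue"))
  expect_equal(vt$neg_log10_p[vt$gene_id == "sox9like"], 34.1878,
               tolerance = 1e-3)
  expect_equal(vt$status[vt$gene_id == "sox9like"], "up")
  expect_equal(vt$status[vt$gene_id == "blue"], "significant_subthreshold")
  expect_equal(attr(vt, "cutoff"), 1)
  expect_equal(as.vector(table(vt$status)[c("up")]),
               sum(de$status == "up"))
})

test_that("the pipeline runs end to end, deterministically, on files", {
  dir <- withr::local_tempdir()
  fx <- makeFixture("tiny", dir = file.path(dir, "in"), seed = 25)
  gmt <- file.path(dir, "sets.gmt")
  writeLines(paste(c("setA", "na", geneIds(fx$annotation)[1:10]),
                   collapse = "\t"), gmt)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  res <- runPipeline(file.path(dir, "in", "annotation.gtf"),
                     file.path(dir, "in", "counts.tsv"),
                     file.path(dir, "in", "design.tsv"),
                     out1, gmt = gmt)
  need <- c("size_factors.tsv", "normalized.tsv", "rpkm.tsv",
            "filter_report.tsv", "detected_genes.tsv", "de_SO_vs_2D.tsv",
            "de_SO_vs_8D.tsv", "de_2D_vs_8D.tsv", "venn_SO_vs_2D_SO_vs_8D.tsv",
            "lncrna_context.tsv", "class_distribution.tsv", "candidates.tsv",
            "mds.tsv", "volcano_SO_vs_2D.tsv", "run_manifest.tsv",
            "enrichment_SO_vs_2D_up.tsv")
  for (f in need) expect_true(file.exists(file.path(out1, f)), label = f)

  runPipeline(file.path(dir, "in", "annotation.gtf"),
              file.path(dir, "in", "counts.tsv"),
              file.path(dir, "in", "design.tsv"),
              out2, gmt = gmt)
  for (f in need)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)

  # stage errors carry the stage name
  expect_error(runPipeline(file.path(dir, "in", "annotation.gtf"),
                           file.path(dir, "in", "counts.tsv"),
                           file.path(dir, "nope.tsv"), out2),
               "stage 'read'")
})

test_that("pipeline candidates equal the truth-derived expectation", {
  dir <- withr::local_tempdir()
  fx <- makeFixture("default", dir = file.path(dir, "in"), seed = 26)
  res <- runPipeline(file.path(dir, "in", "annotation.gtf"),
                     file.path(dir, "in", "counts.tsv"),
                     file.path(dir, "in", "design.tsv"),
                     file.path(dir, "out"))
  # brute-force expectation: DE lncRNAs (up/down in some contrast) whose
  # nearest planted partner distance is < 3 kb, per the placement truth
  placed <- fx$placement
  deLnc <- unique(unlist(lapply(res$deTables, function(d)
    d$gene_id[d$status %in% c("up", "down")])))
  nbAll <- bruteNeighbors(fx$annotation)
  nearest <- sapply(placed$lncrna_id, function(id)
    min(abs(nbAll$distance[nbAll$lncrna_id == id])))
  expected <- placed$lncrna_id[placed$lncrna_id %in% deLnc &
                               nearest[placed$lncrna_id] < 3000]
  expect_setequal(res$candidates$lncrna_id, expected)
})
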