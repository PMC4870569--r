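#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate members within a line are counted once. Lines with fewer than
#' three fields raise a parse error naming the line.
#'
#' @param path GMT file.
#' @return named list of character vectors (the sets), with the descriptions
#'   in `attr(x, "description")`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  sets <- list(); desc <- character()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 fields", i))
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional named character vector of set descriptions.
#' @return the path, invisibly.
#' @export
writeGMT <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && nm %in% names(description))
      description[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each set: k = |query intersect set intersect universe|, K = |set
#' intersect universe|, n = |query|, N = |universe|; p is the upper tail
#' P[X >= k] for X ~ Hypergeometric(N, K, n), BH-adjusted across the
#' collection and sorted by p. Query genes outside the universe are dropped
#' with a warning.
#'
#' @param query character vector of gene ids (e.g. an up-regulated DE list).
#' @param sets named list of character vectors from [readGMT()].
#' @param universe character vector of testable gene ids.
#' @return data.frame with columns `set`, `k`, `n`, `K`, `N`, `p`, `fdr`,
#'   sorted by increasing p.
#' @export
hypergeomOverrep <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(query, intersect(sets[[nm]], universe)))
    p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               p = min(max(p, 0), 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p <- pmax(out$p, .Machine$double.xmin)
  out$fdr <- bhAdjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Over-representation of DE lists per contrast
#'
#' Queries are the genes called `up`, `down`, or either, in each contrast;
#' the universe is the set of tested genes of that contrast (conditioning on
#' testability avoids detection bias).
#'
#' @param deTables list of DE tables from [runContrasts()].
#' @param sets gene-set collection from [readGMT()].
#' @param direction `"up"`, `"down"` or `"all"`.
#' @param top keep the top `top` sets per contrast (default 10; NULL keeps
#'   all).
#' @return named list of [hypergeomOverrep()] tables, one per contrast.
#' @export
enrichDELists <- function(deTables, sets, direction = c("up", "down", "all"),
                          top = 10) {
  direction <- match.arg(direction)
  out <- lapply(deTables, function(de) {
    res <- hypergeomOverrep(deGenes(de, direction), sets, de$gene_id)
    if (!is.null(top)) res <- utils::head(res, top)
    res
  })
  out
}
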