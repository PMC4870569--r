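#' Read a gene x sample count matrix from TSV
#'
#' Tab-separated, UTF-8, `#` comment lines ignored; first column holds gene
#' ids, the header row sample ids. Counts must be non-negative integers;
#' violations are reported by cell.
#'
#' @param path TSV file path.
#' @return integer matrix with gene ids as rownames, sample ids as colnames.
#' @export
readCountsTSV <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts TSV needs a gene_id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in counts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample ids in counts header")
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCountsTSV <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Two columns, `sample` and `group`; every sample must appear exactly once.
#'
#' @param path TSV file path.
#' @param counts optional count matrix to cross-check sample ids against.
#' @return data.frame with columns `sample` and `group`.
#' @export
readDesignTSV <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("design TSV needs 'sample' and 'group' columns")
  df$sample <- as.character(df$sample)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample))
    stop("duplicate sample in design: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (!is.null(counts)) {
    extra <- setdiff(df$sample, colnames(counts))
    missing <- setdiff(colnames(counts), df$sample)
    if (length(extra) || length(missing))
      stop("design/counts sample mismatch; design-only: [",
           paste(extra, collapse = ", "), "] counts-only: [",
           paste(missing, collapse = ", "), "]")
  }
  df[, c("sample", "group")]
}

#' Write a design table as TSV
#' @param design data.frame with `sample` and `group` columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDesignTSV <- function(design, path) {
  utils::write.table(design[, c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Uniform writer for result tables: TSV, no quoting, no rownames.
writeResultTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a UUOSet from counts and design
#'
#' @param counts integer gene x sample matrix (e.g. from [readCountsTSV()]).
#' @param design data.frame with `sample` and `group` (e.g. from
#'   [readDesignTSV()]); order is aligned to the count columns.
#' @param contrasts list of `c(reference, test)` group pairs; defaults to the
#'   study's three comparisons SO vs 2D, SO vs 8D and 2D vs 8D when those
#'   groups are present, otherwise all ordered pairs of observed groups.
#' @return a validated [UUOSet-class].
#' @export
UUOSet <- function(counts, design, contrasts = NULL) {
  if (!setequal(colnames(counts), design$sample))
    stop("design samples must match count matrix columns")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  if (is.null(contrasts)) {
    grp <- unique(design$group)
    contrasts <- if (all(c("SO", "2D", "8D") %in% grp)) {
      list(c("SO", "2D"), c("SO", "8D"), c("2D", "8D"))
    } else {
      utils::combn(grp, 2, simplify = FALSE)
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(group = design$group, row.names = design$sample)
  )
  obj <- methods::new("UUOSet", se)
  metadata(obj)$contrasts <- contrasts
  methods::validObject(obj)
  obj
}

#' Contrasts of a UUOSet
#' @param x a [UUOSet-class].
#' @return list of `c(reference, test)` character pairs.
#' @export
contrastList <- function(x) metadata(x)$contrasts

#' Sample groups of a UUOSet
#' @param x a [UUOSet-class].
#' @return character vector of group labels named by sample.
#' @export
sampleGroups <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                  colnames(x))
}
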