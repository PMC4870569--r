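#' Transcription-factor fold-change table
#'
#' The published table of 42 transcription factors and regulators
#' up-regulated during the UUO fibrosis time course, with linear fold
#' change, log2 fold change and p-value for the SO vs 2D and SO vs 8D
#' comparisons (NA where a gene was not significant in a comparison).
#' Useful as worked-example input: the printed linear and log2 columns are
#' internally consistent and several rows exercise every volcano status
#' class of [classifyStatus()].
#'
#' @return data.frame with columns `gene`, `fc_so_2d`, `log2fc_so_2d`,
#'   `p_so_2d`, `fc_so_8d`, `log2fc_so_8d`, `p_so_8d`.
#' @examples
#' tf <- tfFoldChanges()
#' nrow(tf)   # 42 regulators
#' # printed log2 values reproduce log2 of the linear fold changes
#' max(abs(log2(tf$fc_so_2d) - tf$log2fc_so_2d))
#' @export
tfFoldChanges <- function() {
  path <- system.file("extdata", "tf_fold_changes.tsv", package = "uuoSeq",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
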