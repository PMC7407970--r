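#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header row, no quoting and no row
#' names: the on-disk dialect used by every pipeline stage.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a count matrix as TSV
#'
#' Features in rows; the first column (`feature`) holds feature ids and
#' the remaining columns are samples.
#'
#' @param counts numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' Read a count matrix written by [write_counts_tsv()]
#'
#' @param path file path.
#' @return numeric matrix, features in rows.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
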