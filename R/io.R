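# Plain-text IO: expression matrices as TSV (features in rows, header row of
# sample IDs) and FASTA via Biostrings.

#' Read / write an expression matrix as TSV
#'
#' Layout: features in rows, samples in columns, first column the feature
#' identifier, header row of sample IDs.
#'
#' @param path File path.
#' @return `read_expression_tsv`: a numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  if (anyDuplicated(rownames(m))) stop("duplicate feature identifiers in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in ", path)
  m
}

#' @rdname read_expression_tsv
#' @param matrix Numeric matrix, features in rows.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot(is.matrix(matrix))
  df <- data.frame(feature = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a single sequence as FASTA
#'
#' @param path File path.
#' @return `read_fasta_sequence`: a named character vector of length 1.
#' @export
read_fasta_sequence <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta_sequence
#' @param sequence A DNA string.
#' @param name Record name.
#' @export
write_fasta_sequence <- function(sequence, path, name = "seq") {
  set <- Biostrings::DNAStringSet(stats::setNames(sequence, name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
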