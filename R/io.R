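#' @title Tabular input/output helpers
#'
#' @description
#' Plain TSV readers/writers for the six pipeline input tables and the
#' per-stage outputs. All tables are tab-separated with a header row;
#' gene lists are one symbol per line.
#'
#' @name io
NULL

#' Write a data frame as TSV
#' @param x data frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header
#' @param path input file.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix with its sample-label sidecar
#'
#' The matrix goes to `path` (genes in rows, first column `gene`), the
#' labels to `paste0(path, ".labels")` (columns `sample`, `label`).
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param labels character vector, one of "tumor"/"normal" per sample.
#' @param path output file.
#' @export
write_expression <- function(expr, labels, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write_tsv(df, path)
  write_tsv(
    data.frame(sample = colnames(expr), label = labels),
    paste0(path, ".labels")
  )
  invisible(path)
}

#' Read an expression matrix and its sample-label sidecar
#' @param path file written by [write_expression()].
#' @return list with `expr` (matrix) and `labels` (character vector).
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df$gene
  lab <- read_tsv(paste0(path, ".labels"))
  stopifnot(identical(lab$sample, colnames(expr)))
  list(expr = expr, labels = lab$label)
}

#' Write a gene list, one symbol per line
#' @param genes character vector.
#' @param path output file.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a gene list written by [write_gene_list()]
#' @param path input file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  readLines(path)
}
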