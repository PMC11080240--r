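## Readers and writers for the on-disk formats: genotype CSVs, response
## triples, index files, prediction tables. All writers emit sorted,
## canonical output so identical objects serialize byte-identically.

#' Read / write a genotype matrix CSV
#'
#' Format: header row of gene ids, first column \code{cell_id}, one row per
#' cell line.
#'
#' @param path CSV path.
#' @return numeric matrix with cell ids as rownames, gene ids as colnames.
#' @export
readGenotypeMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readGenotypeMatrix
#' @param m matrix with cell rownames and gene colnames.
#' @export
writeGenotypeMatrix <- function(m, path) {
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write response triples
#'
#' Headerless TSV: \code{cell_id<TAB>drug_id<TAB>auc}. AUC values outside
#' \[0, 1\] are tolerated with a warning (dataset noise), non-numeric values
#' are an error.
#'
#' @param path TSV path.
#' @return data.frame(cell_id, drug_id, auc).
#' @export
readResponseTriples <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("cell_id", "drug_id", "auc"),
                          colClasses = c("character", "character", "numeric"))
  out <- df$auc < 0 | df$auc > 1
  if (any(out)) {
    warning(sprintf("%d AUC values outside [0, 1] (range %.3f..%.3f)",
                    sum(out), min(df$auc), max(df$auc)), call. = FALSE)
  }
  df
}

#' @rdname readResponseTriples
#' @param triples data.frame(cell_id, drug_id, auc).
#' @export
writeResponseTriples <- function(triples, path) {
  utils::write.table(triples[, c("cell_id", "drug_id", "auc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write 0-based index files
#'
#' Format: \code{index<TAB>name}, one entry per line, indices 0-based.
#'
#' @param path file path.
#' @return character vector of names, ordered by index.
#' @export
readIndexFile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("index", "name"),
                          colClasses = c("integer", "character"))
  df$name[order(df$index)]
}

#' @rdname readIndexFile
#' @param names character vector (position i gets index i-1).
#' @export
writeIndexFile <- function(names, path) {
  writeLines(sprintf("%d\t%s", seq_along(names) - 1L, names), path)
  invisible(path)
}

#' Read / write prediction tables
#'
#' TSV with header: \code{cell_id<TAB>drug_id<TAB>predicted_auc}.
#'
#' @param path TSV path.
#' @return data.frame(cell_id, drug_id, predicted_auc).
#' @export
readPredictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
}

#' @rdname readPredictions
#' @param pred data.frame(cell_id, drug_id, predicted_auc).
#' @export
writePredictions <- function(pred, path) {
  utils::write.table(pred[, c("cell_id", "drug_id", "predicted_auc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
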