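# Delimited-text readers and writers for the pipeline's file interfaces:
# drug tables, synergy tables, profile matrices, landmark lists and
# fingerprint dumps. All files are UTF-8 with a header row.

#' Read a drug table (id, smiles)
#'
#' @param path Delimited text file with header columns `id` and `smiles`.
#' @param sep Field separator; default comma.
#' @return Data frame with `id`, `smiles`.
#' @export
read_drug_table <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  if (!all(c("id", "smiles") %in% names(d))) {
    stop_domain("drug table must have header columns 'id' and 'smiles'")
  }
  d[, c("id", "smiles")]
}

#' Read a synergy-record table
#'
#' Expects header columns `drug_a`, `drug_b`, `cell_line` and (optionally)
#' `score`. Drug-order duplicates of the same trio are collapsed by
#' averaging, with a warning.
#'
#' @inheritParams read_drug_table
#' @return Deduplicated synergy record data frame.
#' @export
read_synergy_table <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  dedupe_records(d)
}

#' Read a cell-by-gene profile matrix
#'
#' First column is the cell-line id; remaining columns are named by gene
#' symbol.
#'
#' @inheritParams read_drug_table
#' @return Numeric matrix with cell ids as row names.
#' @export
read_profile_matrix <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1L]])
  m
}

#' Write a cell-by-gene profile matrix
#'
#' @param m Matrix with cell ids as row names.
#' @param path Destination.
#' @param sep Field separator; default tab.
#' @param id_col Name of the leading id column.
#' @export
write_profile_matrix <- function(m, path, sep = "\t", id_col = "cell_id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- id_col
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a landmark gene list (one symbol per line)
#'
#' @param path Text file.
#' @return Character vector of symbols.
#' @export
read_landmark <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write fingerprint vectors as delimited text
#'
#' One row per drug: the id followed by the 0/1 bits; round-trips through
#' [read_fingerprints()].
#'
#' @param fp Drugs-by-bits matrix with drug ids as row names (one kind).
#' @param path Destination.
#' @param sep Field separator; default comma.
#' @export
write_fingerprints <- function(fp, path, sep = ",") {
  d <- data.frame(id = rownames(fp), fp, check.names = FALSE)
  colnames(d) <- c("id", paste0("b", seq_len(ncol(fp))))
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read fingerprint vectors written by [write_fingerprints()]
#'
#' @inheritParams read_drug_table
#' @return Integer drugs-by-bits matrix with drug ids as row names.
#' @export
read_fingerprints <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(d[[1L]])
  dimnames(m)[[2]] <- NULL
  m
}

#' Write a complete synthetic study to disk
#'
#' Emits the same file formats the pipeline consumes: `drugs.csv`,
#' `synergy.csv`, `expression.tsv`, `mutation.tsv` and `landmark.txt` (the
#' expression panel symbols).
#'
#' @param dataset Output of [generate_synergy_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synergy_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(dataset$drugs, file.path(dir, "drugs.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$records, file.path(dir, "synergy.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_profile_matrix(dataset$features$expression,
                       file.path(dir, "expression.tsv"))
  write_profile_matrix(dataset$features$mutation,
                       file.path(dir, "mutation.tsv"))
  writeLines(dataset$panel$expression_genes, file.path(dir, "landmark.txt"))
  invisible(dir)
}

#' Write a metrics report (or a list of them) as JSON
#'
#' @param x A `metrics_report`, or a named list of them.
#' @param path Destination JSON file.
#' @export
write_metrics_json <- function(x, path) {
  strip <- function(r) list(rmse = r$rmse, r2 = r$r2, pcc = r$pcc, n = r$n)
  out <- if (inherits(x, "metrics_report")) strip(x) else lapply(x, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
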