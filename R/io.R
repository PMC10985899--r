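# Delimited-text I/O: triplet tables, expression matrices, gene panels and
# attention reports. CSV/TSV is the de facto interchange format for synergy
# screens; SMILES are kept verbatim.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read labeled synergy triplets from delimited text
#'
#' Expects a header with `drug_a`, `drug_b`, `cell_line` and either `label`
#' (0/1) or `loewe_score`; scores are routed through [label_by_loewe()] and
#' dead-zone rows dropped with a message. Malformed rows are reported with
#' their file line numbers.
#'
#' @param path CSV or TSV file path.
#' @return Data.frame with `drug_a`, `drug_b`, `cell_line`, `label` (and
#'   `loewe_score` when present).
#' @export
read_triplets <- function(path) {
  if (!file.exists(path)) stop(sprintf("triplet file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("drug_a", "drug_b", "cell_line")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!any(c("label", "loewe_score") %in% names(df)))
    stop(sprintf("%s: needs a 'label' or 'loewe_score' column", path),
         call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  self <- df$drug_a == df$drug_b
  if (any(self))
    stop(sprintf("%s: self-pair (drug_a == drug_b) on line(s): %s", path,
                 paste(line_no[self], collapse = ", ")), call. = FALSE)
  if ("label" %in% names(df)) {
    bad <- !(df$label %in% c(0, 1))
    if (any(bad))
      stop(sprintf("%s: label must be 0/1 on line(s): %s", path,
                   paste(line_no[bad], collapse = ", ")), call. = FALSE)
  } else {
    if (!is.numeric(df$loewe_score)) {
      bad <- is.na(suppressWarnings(as.numeric(df$loewe_score)))
      stop(sprintf("%s: non-numeric loewe_score on line(s): %s", path,
                   paste(line_no[bad], collapse = ", ")), call. = FALSE)
    }
    lab <- label_by_loewe(df$loewe_score)
    drop <- is.na(lab)
    if (any(drop))
      message(sprintf("%s: dropped %d dead-zone row(s) (0 <= score <= 10): line(s) %s",
                      path, sum(drop),
                      paste(line_no[drop], collapse = ", ")))
    df <- df[!drop, , drop = FALSE]
    df$label <- lab[!drop]
  }
  rownames(df) <- NULL
  df
}

#' Write triplets to CSV
#' @param triplets Triplet data.frame.
#' @param path Output path.
#' @export
write_triplets <- function(triplets, path) {
  utils::write.csv(triplets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genes-by-cells expression matrix from delimited text
#'
#' First column gene ids, header row cell ids.
#' @param path CSV or TSV file path.
#' @return Numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("expression file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#' @param mat Genes x cells matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene panel (one gene id per line)
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path),
                               call. = FALSE)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write an attention report to CSV
#'
#' @param report Data.frame from [attention_report()].
#' @param path Output path.
#' @return The path, invisibly. Round-trips through
#'   [read_attention_report()] to within 1e-9.
#' @export
write_attention_report <- function(report, path) {
  out <- report
  out$score <- format(out$score, digits = 15, scientific = TRUE, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an attention report written by [write_attention_report()]
#' @param path CSV path.
#' @return Data.frame with numeric `score`.
#' @export
read_attention_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("report not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}

#' Serialize an evaluation report to JSON
#' @param report An `eval_report` from [compute_metrics()].
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
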