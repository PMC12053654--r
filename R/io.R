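## Delimited-text interfaces: expression matrices with sample metadata,
## gene lists, normalization factors and reports. On disk genes are rows
## (the transcriptomics convention); the multivariate stages transpose to
## samples x genes in memory.

#' Write an ExpressionStudy to TSV
#'
#' Writes the genes x samples matrix (first column `gene_id`, header =
#' sample ids) and a sample-metadata TSV (`sample_id`, `study`, `class`,
#' `platform`) alongside.
#'
#' @param study an [expression_study()].
#' @param path path of the matrix TSV; metadata goes to
#'   `<path-sans-ext>_metadata.tsv` unless `metadata_path` is given.
#' @param metadata_path optional explicit metadata path.
#' @return invisibly, the two paths written.
#' @export
write_expression_study <- function(study, path, metadata_path = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (is.null(metadata_path)) {
    metadata_path <- sub("\\.tsv$", "", path)
    metadata_path <- paste0(metadata_path, "_metadata.tsv")
  }
  df <- data.frame(gene_id = study$gene_ids, study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = study$sample_ids, study = study$study_id,
                     class = as.character(study$class_labels),
                     platform = study$platform, stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = path, metadata = metadata_path))
}

#' Read an ExpressionStudy from TSV
#'
#' Expects the layout written by [write_expression_study()]. Duplicate
#' gene ids and missing cells are rejected with the offending ids named.
#'
#' @param path matrix TSV (first column gene ids, header sample ids).
#' @param metadata_path metadata TSV; defaults to the sibling
#'   `_metadata.tsv`.
#' @return an [expression_study()].
#' @export
read_expression_study <- function(path, metadata_path = NULL) {
  if (is.null(metadata_path)) {
    metadata_path <- paste0(sub("\\.tsv$", "", path), "_metadata.tsv")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!ncol(df) || names(df)[1] != "gene_id") stopf("first column must be 'gene_id'")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    stopf("duplicated gene id(s) in %s: %s", path,
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stopf("NA cells in %s", path)
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "study", "class", "platform") %in% names(meta))) {
    stopf("metadata must have columns sample_id, study, class, platform")
  }
  if (!identical(as.character(meta$sample_id), colnames(m))) {
    meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id)) stopf("metadata does not cover all samples")
  }
  expression_study(m, class_labels = meta$class, study_id = meta$study[1],
                   platform = meta$platform[1], gene_ids = gene_ids,
                   sample_ids = colnames(m))
}

#' Read a gene list
#'
#' One id per line; `#` starts a comment; blank lines are skipped. Ids
#' are canonicalized (uppercase) and de-duplicated with a warning,
#' preserving first-occurrence order.
#'
#' @param path text file path.
#' @return character vector of canonical gene ids (possibly empty, with
#'   a warning).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ids <- canonical_gene_id(lines)
  if (anyDuplicated(ids)) {
    warning(sprintf("duplicate gene id(s) dropped: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            call. = FALSE)
    ids <- ids[!duplicated(ids)]
  }
  if (!length(ids)) warning("empty gene list: ", path, call. = FALSE)
  ids
}

#' Write a gene list (one canonical id per line)
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(canonical_gene_id(genes), path)
  invisible(path)
}

#' Serialize a SignatureReport to JSON
#' @param report a [signature_report()].
#' @param path output path.
#' @export
write_signature_report <- function(report, path) {
  stopifnot(inherits(report, "SignatureReport"))
  jsonlite::write_json(list(stages = report$stages,
                            counts = as.list(report$counts)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a SignatureReport back from JSON
#' @param path JSON path written by [write_signature_report()].
#' @return a `SignatureReport`.
#' @export
read_signature_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- x$stages
  as_chr <- function(v) if (is.null(v) || !length(v)) character(0) else as.character(v)
  signature_report(vip_lists = lapply(st$vip, as_chr),
                   intersection = as_chr(st$intersection),
                   q_filtered = as_chr(st$q_filtered),
                   aligned = as_chr(st$aligned),
                   tuned = as_chr(st$tuned))
}
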