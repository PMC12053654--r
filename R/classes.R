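## Core S3 containers: ExpressionStudy and StudyCollection.

#' Construct an ExpressionStudy
#'
#' A single study's genes x samples expression matrix together with its
#' sample class labels, platform and study identifier. RNA-seq studies
#' hold non-negative integer counts; microarray studies hold log2
#' intensities.
#'
#' @param matrix numeric genes x samples matrix. Row names are gene ids,
#'   column names are sample ids (supplied names win over `gene_ids` /
#'   `sample_ids` arguments when both are given and equal).
#' @param class_labels factor or character vector of per-sample class
#'   labels (e.g. `lean`/`obese` or `R`/`I`/`P`).
#' @param study_id single character study identifier.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param gene_ids,sample_ids optional explicit id vectors; default to the
#'   dimnames of `matrix`.
#' @param species optional annotation (`"mouse"`, `"human"`, ...), used
#'   only for reporting.
#' @return An object of class `ExpressionStudy`.
#' @export
expression_study <- function(matrix, class_labels, study_id,
                             platform = c("microarray", "rnaseq"),
                             gene_ids = rownames(matrix),
                             sample_ids = colnames(matrix),
                             species = NA_character_) {
  platform <- match.arg(platform)
  matrix <- as.matrix(matrix)
  if (is.null(gene_ids)) stopf("gene ids are required (rownames or 'gene_ids')")
  if (is.null(sample_ids)) sample_ids <- paste0(study_id, "_s", seq_len(ncol(matrix)))
  if (length(gene_ids) != nrow(matrix)) {
    stopf("length of gene_ids (%d) != nrow(matrix) (%d)", length(gene_ids), nrow(matrix))
  }
  if (length(sample_ids) != ncol(matrix)) {
    stopf("length of sample_ids (%d) != ncol(matrix) (%d)", length(sample_ids), ncol(matrix))
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stopf("duplicated gene ids: %s", paste(utils::head(dups, 5L), collapse = ", "))
  }
  if (anyNA(matrix)) stopf("expression matrix contains missing values")
  if (length(class_labels) != ncol(matrix)) {
    stopf("class_labels length (%d) != number of samples (%d)",
          length(class_labels), ncol(matrix))
  }
  if (platform == "rnaseq") {
    if (any(matrix < 0)) stopf("rnaseq counts must be non-negative")
    if (any(abs(matrix - round(matrix)) > 1e-8)) {
      stopf("rnaseq counts must be integer-valued")
    }
  }
  dimnames(matrix) <- list(gene_ids, sample_ids)
  structure(list(
    study_id = as.character(study_id),
    platform = platform,
    matrix = matrix,
    gene_ids = as.character(gene_ids),
    sample_ids = as.character(sample_ids),
    class_labels = factor(class_labels),
    species = species
  ), class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s' (%s): %d genes x %d samples\n",
              x$study_id, x$platform, nrow(x$matrix), ncol(x$matrix)))
  cat("  classes:", paste(sprintf("%s=%d", levels(x$class_labels),
                                  tabulate(x$class_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$matrix)

#' Assemble a StudyCollection from a list of ExpressionStudy objects
#'
#' Gene identifiers are canonicalized through an ortholog map (by default
#' case-insensitive symbol identity, see [canonical_gene_id()]) and the
#' shared gene panel is the intersection of every study's canonical panel.
#'
#' @param studies list of [expression_study()] objects.
#' @param ortholog_map optional data frame with columns `source_id` and
#'   `canonical_id` overriding the default case-insensitive mapping for the
#'   ids it covers.
#' @return A `StudyCollection` with elements `studies`, `shared_genes`
#'   (canonical ids present in every study), `study_vector` and
#'   `class_vector` (per sample over the concatenated collection), and
#'   `truth` (planted-signature bookkeeping when built by the simulator).
#' @export
study_collection <- function(studies, ortholog_map = NULL) {
  if (!length(studies)) stopf("at least one study is required")
  if (!all(vapply(studies, inherits, logical(1), "ExpressionStudy"))) {
    stopf("'studies' must be a list of ExpressionStudy objects")
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stopf("duplicated study ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  panels <- lapply(studies, function(s) map_gene_ids(s$gene_ids, ortholog_map))
  shared <- Reduce(intersect, panels)
  if (!length(shared)) stopf("no genes are shared by all studies after ortholog mapping")
  study_vector <- factor(rep(ids, vapply(studies, function(s) ncol(s$matrix), integer(1))),
                         levels = ids)
  class_vector <- factor(unlist(lapply(studies, function(s) as.character(s$class_labels))))
  names(studies) <- ids
  structure(list(
    studies = studies,
    shared_genes = shared,
    study_vector = study_vector,
    class_vector = class_vector,
    ortholog_map = ortholog_map,
    truth = NULL
  ), class = "StudyCollection")
}

#' Map source gene ids to canonical ids
#'
#' @param ids character vector of source ids.
#' @param ortholog_map optional data frame (`source_id`, `canonical_id`);
#'   ids not covered by the map fall back to [canonical_gene_id()].
#' @return canonical id vector, same length as `ids`.
#' @export
map_gene_ids <- function(ids, ortholog_map = NULL) {
  out <- canonical_gene_id(ids)
  if (!is.null(ortholog_map)) {
    if (!all(c("source_id", "canonical_id") %in% names(ortholog_map))) {
      stopf("ortholog_map needs columns 'source_id' and 'canonical_id'")
    }
    if (anyDuplicated(ortholog_map$source_id)) {
      stopf("ortholog_map must be a function: duplicated source ids")
    }
    hit <- match(as.character(ids), as.character(ortholog_map$source_id))
    out[!is.na(hit)] <- canonical_gene_id(ortholog_map$canonical_id[hit[!is.na(hit)]])
  }
  out
}

#' @export
print.StudyCollection <- function(x, ...) {
  n <- vapply(x$studies, function(s) ncol(s$matrix), integer(1))
  cat(sprintf("StudyCollection: %d studies, %d total samples, %d shared genes\n",
              length(x$studies), sum(n), length(x$shared_genes)))
  for (s in x$studies) {
    cat(sprintf("  %-12s %-10s %3d genes x %3d samples\n",
                s$study_id, s$platform, nrow(s$matrix), ncol(s$matrix)))
  }
  invisible(x)
}

#' Expression matrix of a study on the analysis (log) scale
#'
#' Microarray studies are already log2 intensities and are returned as-is.
#' RNA-seq studies are TMM-normalized and transformed to log2 CPM so that
#' all platforms enter the multivariate stages on a comparable linear
#' scale.
#'
#' @param study an [expression_study()].
#' @param prior log-CPM prior count for RNA-seq studies (see [log_cpm()]).
#' @return genes x samples numeric matrix on the log2 scale.
#' @export
study_log_matrix <- function(study, prior = 0.5) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (study$platform == "rnaseq") {
    log_cpm(study$matrix, tmm_factors(study$matrix), prior = prior)
  } else {
    study$matrix
  }
}
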