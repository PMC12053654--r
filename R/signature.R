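## The signature workflow: three-way intersection of per-dataset VIP gene
## lists, q-value refinement, cross-study alignment, and loading-based
## ranking of the final panel.

#' Intersect per-dataset discriminant gene lists
#'
#' @param lists list of character vectors of canonical gene ids
#'   (typically the three VIP-selected lists).
#' @return character vector: genes present in every list.
#' @export
intersect_signatures <- function(lists) {
  if (!length(lists)) return(character(0))
  Reduce(intersect, lapply(lists, canonical_gene_id))
}

#' Exclude genes non-significant in every dataset
#'
#' A gene is dropped only when its BH-adjusted q-value exceeds `alpha` in
#' *all* datasets; significance in at least one dataset retains it.
#'
#' @param common character vector of candidate gene ids.
#' @param qtables named list of per-dataset q-value lookups: each element
#'   either a named numeric vector or a `DiffExpTable` (columns `gene`,
#'   `q`).
#' @param alpha significance threshold (default 0.05).
#' @return the retained gene set (input order preserved).
#' @export
exclude_nonsignificant <- function(common, qtables, alpha = 0.05) {
  common <- canonical_gene_id(common)
  qs <- vapply(qtables, function(tab) {
    v <- if (is.data.frame(tab)) stats::setNames(tab$q, canonical_gene_id(tab$gene)) else {
      stats::setNames(as.numeric(tab), canonical_gene_id(names(tab)))
    }
    miss <- setdiff(common, names(v))
    if (length(miss)) {
      stopf("missing q-value for gene(s): %s", paste(utils::head(miss, 5L), collapse = ", "))
    }
    v[common]
  }, numeric(length(common)))
  qs <- matrix(qs, nrow = length(common))
  drop_all <- apply(qs > alpha, 1, all)
  common[!drop_all]
}

#' Align a gene set across every study of a collection
#'
#' Keeps the genes whose canonical id is present in every study's panel
#' (post-dropout, under the ortholog map) and restricts the collection's
#' shared panel to them.
#'
#' @param coll a [study_collection()].
#' @param genes candidate gene ids.
#' @param ortholog_map optional override of the collection's map.
#' @return list with `genes` (the surviving set, in input order) and
#'   `collection` (with `shared_genes` restricted to the survivors).
#' @export
align_across_studies <- function(coll, genes, ortholog_map = coll$ortholog_map) {
  stopifnot(inherits(coll, "StudyCollection"))
  genes <- canonical_gene_id(genes)
  panels <- lapply(coll$studies, function(s) map_gene_ids(s$gene_ids, ortholog_map))
  present_all <- Reduce(intersect, panels)
  survivors <- genes[genes %in% present_all]
  if (!length(survivors)) stopf("no candidate gene survives alignment across all studies")
  coll$shared_genes <- survivors
  list(genes = survivors, collection = coll)
}

#' Rank genes by integration-model loading
#'
#' Genes are ordered by decreasing absolute loading on the chosen
#' component; ties break lexicographically by id. An optional cutoff on
#' the absolute loading (strict `>`) truncates the table for display.
#'
#' @param m a fitted `MINTModel` (or `PLSModel`).
#' @param component component index (default 1).
#' @param cutoff optional display cutoff on `|loading|`.
#' @return data frame `gene`, `loading`, `abs_loading`, `rank`.
#' @export
rank_by_loading <- function(m, component = 1L, cutoff = NULL) {
  if (component > m$ncomp) stopf("component %d > ncomp = %d", component, m$ncomp)
  w <- m$weights[, component]
  ord <- order(-abs(w), names(w))
  out <- data.frame(gene = names(w)[ord], loading = unname(w[ord]),
                    abs_loading = abs(unname(w[ord])),
                    rank = seq_along(w), stringsAsFactors = FALSE)
  if (!is.null(cutoff)) out <- out[out$abs_loading > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a stage-wise signature report
#'
#' Records the gene set surviving each stage of the discovery workflow
#' and validates the nesting invariant
#' `tuned` \eqn{\subseteq} `aligned` \eqn{\subseteq} `q_filtered`
#' \eqn{\subseteq} `intersection` \eqn{\subseteq} each VIP list.
#'
#' @param vip_lists named list of the per-dataset VIP-selected gene sets.
#' @param intersection,q_filtered,aligned,tuned successive stage sets.
#' @param statistics optional per-gene statistics data frame (VIPs,
#'   q-values, loadings, ranks).
#' @return a `SignatureReport` list with `stages`, `counts`,
#'   `statistics`.
#' @export
signature_report <- function(vip_lists, intersection, q_filtered, aligned,
                             tuned = aligned, statistics = NULL) {
  stages <- list(intersection = intersection, q_filtered = q_filtered,
                 aligned = aligned, tuned = tuned)
  stages <- lapply(stages, canonical_gene_id)
  vip_lists <- lapply(vip_lists, canonical_gene_id)
  for (nm in names(vip_lists)) {
    if (!all(stages$intersection %in% vip_lists[[nm]])) {
      stopf("nesting violation: intersection is not a subset of VIP list '%s'", nm)
    }
  }
  chain <- c("intersection", "q_filtered", "aligned", "tuned")
  for (i in seq_len(length(chain) - 1L)) {
    if (!all(stages[[chain[i + 1L]]] %in% stages[[chain[i]]])) {
      stopf("nesting violation: stage '%s' is not a subset of stage '%s'",
            chain[i + 1L], chain[i])
    }
  }
  structure(list(
    stages = c(list(vip = vip_lists), stages),
    counts = c(vapply(vip_lists, length, integer(1)),
               vapply(stages, length, integer(1))),
    statistics = statistics
  ), class = "SignatureReport")
}

#' @export
print.SignatureReport <- function(x, ...) {
  cat("SignatureReport\n")
  for (nm in names(x$counts)) cat(sprintf("  %-14s %d genes\n", nm, x$counts[[nm]]))
  invisible(x)
}
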