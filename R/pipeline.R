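## End-to-end discovery workflow: per-dataset differential screening and
## PLS-DA/VIP selection, three-way intersection, q-value refinement,
## cross-study alignment, and (optionally tuned) sparse multi-study
## integration with loading-based ranking.

## Per-dataset analysis matrix on the log scale, with the RNA-seq
## low-expression filter applied before normalization.
prepare_single_study <- function(study, min_mean_cpm = 10, prior = 0.5) {
  if (study$platform == "rnaseq") {
    counts <- filter_low_expression(study$matrix, min_mean_cpm)
    log_cpm(counts, tmm_factors(counts), prior = prior)
  } else {
    study$matrix
  }
}

#' Analyse one dataset: differential screening plus PLS-DA/VIP selection
#'
#' @param study an [expression_study()] with >= 2 classes.
#' @param vip_threshold VIP selection threshold (default 1.5).
#' @param ncomp PLS-DA components (default: number of classes - 1).
#' @param min_mean_cpm RNA-seq low-expression filter threshold.
#' @param permute_B if positive, also run [permutation_test()] with this
#'   many permutations (500 at study scale).
#' @param seed seed for the permutation test.
#' @return list with `vip_selected` (canonical ids), `vip` (full vector,
#'   canonical names), `diffexp` (q-table with canonical ids), `model`,
#'   and optionally `permutation`.
#' @export
analyse_single_study <- function(study, vip_threshold = 1.5, ncomp = NULL,
                                 min_mean_cpm = 10, permute_B = 0L, seed = 1L) {
  stopifnot(inherits(study, "ExpressionStudy"))
  M <- prepare_single_study(study, min_mean_cpm)
  rownames(M) <- canonical_gene_id(rownames(M))
  y <- droplevels(study$class_labels)
  if (is.null(ncomp)) ncomp <- max(1L, nlevels(y) - 1L)
  de <- per_gene_f_test(M, y)
  model <- fit_plsda(t(M), y, ncomp = ncomp)
  v <- vip(model)
  out <- list(vip_selected = select_by_vip(v, vip_threshold),
              vip = v, diffexp = de, model = model)
  if (permute_B > 0L) {
    out$permutation <- permutation_test(t(M), y, ncomp = ncomp, B = permute_B,
                                        seed = seed)
  }
  out
}

#' Discover a cross-study predictive gene signature
#'
#' Runs the full marker-discovery workflow: each input dataset is
#' screened (per-gene ANOVA with BH adjustment) and modelled by PLS-DA
#' with VIP selection; the per-dataset VIP lists are intersected; genes
#' whose q-value exceeds `alpha` in *every* dataset are excluded; the
#' survivors are aligned across the integration collection's studies;
#' and a MINT (sparse) PLS-DA on the aligned panel ranks the final genes
#' by their component-1 loadings, optionally after tuning keepX by
#' leave-one-study-out BER.
#'
#' @param studies named list of >= 2 [expression_study()] datasets (the
#'   canonical design uses three).
#' @param collection a [study_collection()] for the integration stage.
#' @param vip_threshold VIP selection threshold (default 1.5).
#' @param alpha q-value threshold for the exclusion rule (default 0.05).
#' @param min_mean_cpm RNA-seq filter threshold (default 10).
#' @param mint_ncomp components of the integration model (default 1).
#' @param tune tune keepX by [tune_keepx()]? (default FALSE: dense).
#' @param keepx_grid candidate keepX values; default
#'   `c(5, 10, 20, 35, 50, 75, 100, panel size)` clipped to the panel.
#' @param permute_B per-dataset permutation count (0 = skip).
#' @param seed seed for stochastic stages.
#' @return list with `report` (a [signature_report()]), `ranking`
#'   (loading table), `mint_model`, `tuning` (NULL unless tuned), and
#'   `single` (per-dataset results).
#' @export
discover_signature <- function(studies, collection, vip_threshold = 1.5,
                               alpha = 0.05, min_mean_cpm = 10,
                               mint_ncomp = 1L, tune = FALSE,
                               keepx_grid = NULL, permute_B = 0L, seed = 1L) {
  if (length(studies) < 2L) stopf("need >= 2 discovery datasets")
  if (is.null(names(studies))) {
    names(studies) <- vapply(studies, `[[`, character(1), "study_id")
  }
  single <- lapply(studies, analyse_single_study, vip_threshold = vip_threshold,
                   min_mean_cpm = min_mean_cpm, permute_B = permute_B, seed = seed)
  vip_lists <- lapply(single, `[[`, "vip_selected")
  common <- intersect_signatures(vip_lists)
  qtables <- lapply(single, `[[`, "diffexp")
  refined <- exclude_nonsignificant(common, qtables, alpha = alpha)
  al <- align_across_studies(collection, refined)
  panel <- al$genes
  tuning <- NULL
  keepX <- length(panel)
  if (tune) {
    if (is.null(keepx_grid)) {
      keepx_grid <- c(5, 10, 20, 35, 50, 75, 100, length(panel))
    }
    keepx_grid <- unique(pmin(keepx_grid, length(panel)))
    tuning <- tune_keepx(al$collection, grid = keepx_grid, ncomp = 1L)
    keepX <- tuning$choice
  }
  mm <- fit_mint_splsda(al$collection, ncomp = mint_ncomp, keepX = keepX,
                        genes = panel)
  tuned <- rownames(mm$weights)[rowSums(abs(mm$weights)) > 0]
  ranking <- rank_by_loading(mm, component = 1L)
  report <- signature_report(vip_lists = vip_lists, intersection = common,
                             q_filtered = refined, aligned = panel,
                             tuned = tuned)
  list(report = report, ranking = ranking, mint_model = mm,
       tuning = tuning, single = single)
}
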