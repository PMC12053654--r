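## Sparse PLS-DA and multi-study (MINT) PLS-DA / sparse PLS-DA with
## leave-one-study-out cross-validation, keepX tuning and ROC/AUC.
##
## The multi-study fits center and unit-scale each study's columns with
## that study's own statistics, so additive study-level batch offsets are
## absorbed by construction; global weight vectors are estimated on the
## concatenated within-study-standardized data, and deflation is carried
## out per study with study-specific (partial) scores and loadings.

#' Fit a sparse PLS-DA model
#'
#' PLS-DA in which each component's X-weight vector is constrained to
#' exactly `keepX` nonzero entries via soft-thresholding at the magnitude
#' of the (keepX+1)-th largest weight (the standard lasso surrogate of
#' sparse PLS), renormalized inside the NIPALS iterations.
#'
#' @inheritParams fit_plsda
#' @param keepX integer (recycled per component): number of variables
#'   retained on each component. `keepX = ncol(X)` reproduces the dense
#'   fit.
#' @return a `PLSModel` (see [fit_plsda()]) with the sparsity recorded in
#'   `keepX`.
#' @export
fit_splsda <- function(X, y, ncomp = 2L, keepX = ncol(as.matrix(X)), scale = TRUE) {
  fit_plsda(X, y, ncomp = ncomp, scale = scale, keepX = keepX)
}

## Assemble the per-study standardized blocks of a collection restricted
## to the shared panel (or a subset of it), samples x genes, with each
## study's own centering/scaling statistics.
mint_blocks <- function(coll, genes = coll$shared_genes, scale = TRUE) {
  stopifnot(inherits(coll, "StudyCollection"))
  genes <- intersect(genes, coll$shared_genes)
  if (!length(genes)) stopf("empty gene panel")
  lapply(coll$studies, function(s) {
    canon <- map_gene_ids(s$gene_ids, coll$ortholog_map)
    M <- study_log_matrix(s)
    rownames(M) <- canon
    Xs <- t(M[genes, , drop = FALSE])
    if (nrow(Xs) < 2L) stopf("study '%s' has a single sample; scaling undefined", s$study_id)
    cs <- center_scale(Xs, scale, sprintf("X (study %s)", s$study_id))
    list(X = cs$M, center = cs$center, scale = cs$scale,
         y = factor(as.character(s$class_labels)), study_id = s$study_id)
  })
}

#' Fit a multi-study (MINT) PLS-DA model
#'
#' Horizontal integration of several studies measured on a shared gene
#' panel: each study's columns are centered and unit-scaled with its own
#' statistics, global components are estimated on the concatenated
#' standardized data, and deflation uses study-specific partial scores
#' and loadings so study-level variation is controlled throughout.
#'
#' @param coll a [study_collection()] (RNA-seq studies are transformed to
#'   TMM log-CPM internally, see [study_log_matrix()]).
#' @param ncomp number of components (default 5).
#' @param keepX optional per-component nonzero-loading counts (sparse
#'   fit); default dense.
#' @param genes optional subset of the shared panel to model.
#' @param scale scale columns to unit variance per study (default TRUE).
#' @return a `MINTModel`: global `weights` (the per-gene loadings used
#'   for ranking), `y_loadings`, global `scores`, `partial_scores` (per
#'   study), per-study centering/scaling statistics, class `levels`,
#'   `ncomp`, `keepX`, explained variances and the gene panel.
#' @export
fit_mint_plsda <- function(coll, ncomp = 5L, keepX = NULL,
                           genes = coll$shared_genes, scale = TRUE) {
  blocks <- mint_blocks(coll, genes, scale)
  genes <- colnames(blocks[[1]]$X)
  p <- length(genes)
  y_all <- factor(unlist(lapply(blocks, function(b) as.character(b$y))))
  if (nlevels(y_all) < 2L) stopf("need >= 2 classes across the collection")
  lev <- levels(y_all)
  n_m <- vapply(blocks, function(b) nrow(b$X), integer(1))
  if (ncomp > min(sum(n_m) - 1L, p)) stopf("ncomp too large for the panel")
  keepX <- if (is.null(keepX)) rep(p, ncomp) else rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1L) || any(keepX > p)) stopf("keepX must lie in [1, %d]", p)

  ## per-study standardized dummy responses
  Ys <- lapply(blocks, function(b) {
    Y <- outer(as.character(b$y), lev, "==") + 0
    colnames(Y) <- lev
    ctr <- colMeans(Y)
    scl <- apply(Y, 2, stats::sd)
    scl[scl == 0] <- 1          # class absent from this study
    sweep(sweep(Y, 2, ctr), 2, scl, "/")
  })
  Xs <- lapply(blocks, `[[`, "X")
  idx <- rep(seq_along(blocks), n_m)

  W <- matrix(0, p, ncomp, dimnames = list(genes, NULL))
  Q <- matrix(0, length(lev), ncomp, dimnames = list(lev, NULL))
  Tm <- matrix(0, sum(n_m), ncomp)
  ssy <- numeric(ncomp); ssx <- numeric(ncomp)
  ssx_tot <- sum(vapply(Xs, function(M) sum(M^2), numeric(1)))
  ssy_tot <- sum(vapply(Ys, function(M) sum(M^2), numeric(1)))
  for (h in seq_len(ncomp)) {
    Xc <- do.call(rbind, Xs)
    Yc <- do.call(rbind, Ys)
    ## one NIPALS pass on the concatenated standardized data
    u <- Yc[, which.max(colSums(Yc^2))]
    w_old <- rep(0, p)
    for (it in seq_len(1000L)) {
      w <- drop(crossprod(Xc, u))
      w <- soft_threshold_keepx(w, keepX[h])
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stopf("degenerate component %d", h)
      w <- w / nw
      tt <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
      u <- drop(Yc %*% q) / sum(q^2)
      if (sum((w - w_old)^2) < 1e-14) break
      w_old <- w
    }
    W[, h] <- w; Q[, h] <- q; Tm[, h] <- tt
    pl_global <- drop(crossprod(Xc, tt)) / sum(tt^2)
    ssx[h] <- sum(tt^2) * sum(pl_global^2)
    ssy[h] <- sum(tt^2) * sum(q^2)
    ## per-study deflation with partial scores/loadings
    for (m in seq_along(Xs)) {
      t_m <- drop(Xs[[m]] %*% w)
      p_m <- drop(crossprod(Xs[[m]], t_m)) / sum(t_m^2)
      c_m <- drop(crossprod(Ys[[m]], t_m)) / sum(t_m^2)
      Xs[[m]] <- Xs[[m]] - tcrossprod(t_m, p_m)
      Ys[[m]] <- Ys[[m]] - tcrossprod(t_m, c_m)
    }
  }
  partial <- split.data.frame(Tm, idx)
  names(partial) <- names(blocks)
  ## overall dummy means: prediction offset
  Yd <- outer(as.character(y_all), lev, "==") + 0
  structure(list(
    weights = W, y_loadings = Q, scores = Tm,
    partial_scores = lapply(partial, as.matrix),
    x_center = lapply(blocks, `[[`, "center"),
    x_scale = lapply(blocks, `[[`, "scale"),
    y_center = colMeans(Yd),
    levels = lev, y = y_all, ncomp = ncomp, keepX = keepX,
    study_ids = names(blocks),
    study_vector = factor(rep(names(blocks), n_m), levels = names(blocks)),
    gene_ids = genes, scale = scale,
    expl_x = ssx / ssx_tot, expl_y = ssy / ssy_tot, ssy = ssy
  ), class = "MINTModel")
}

#' Fit a sparse multi-study (MINT sparse PLS-DA) model
#'
#' As [fit_mint_plsda()] with the per-component `keepX` sparsity
#' constraint of [fit_splsda()] on the global loadings.
#'
#' @inheritParams fit_mint_plsda
#' @param keepX integer (recycled per component): nonzero global
#'   loadings per component.
#' @return a `MINTModel`.
#' @export
fit_mint_splsda <- function(coll, ncomp = 1L, keepX,
                            genes = coll$shared_genes, scale = TRUE) {
  fit_mint_plsda(coll, ncomp = ncomp, keepX = keepX, genes = genes, scale = scale)
}

#' @export
print.MINTModel <- function(x, ...) {
  cat(sprintf("MINTModel: %d studies, %d components, %d genes, classes: %s\n",
              length(x$study_ids), x$ncomp, length(x$gene_ids),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict classes for a new study with a MINT model
#'
#' The new study is centered and unit-scaled with its *own* statistics
#' (the contract that makes cross-platform transfer possible), projected
#' on the global loadings with study-side deflation mirroring training,
#' and classified by maximum predicted dummy score or nearest centroid.
#'
#' @param m a fitted `MINTModel`.
#' @param Xnew samples x genes matrix (>= 2 samples) over the model's
#'   gene panel, log scale.
#' @param distance `"max"` or `"centroid"`.
#' @param ncomp components used (default all).
#' @return list with `class`, `scores` (per-class predicted values) and
#'   `projection` (new-study partial scores).
#' @export
predict_mint <- function(m, Xnew, distance = c("max", "centroid"),
                         ncomp = m$ncomp) {
  stopifnot(inherits(m, "MINTModel"))
  distance <- match.arg(distance)
  Xnew <- as.matrix(Xnew)
  if (!is.null(colnames(Xnew)) && !identical(colnames(Xnew), m$gene_ids)) {
    if (!setequal(colnames(Xnew), m$gene_ids)) stopf("gene panel mismatch")
    Xnew <- Xnew[, m$gene_ids, drop = FALSE]
  }
  if (nrow(Xnew) < 2L) stopf("a predicted study needs >= 2 samples (own scaling)")
  cs <- center_scale(Xnew, m$scale, "Xnew")
  Xs <- cs$M
  Tnew <- matrix(0, nrow(Xs), ncomp)
  for (h in seq_len(ncomp)) {
    tt <- drop(Xs %*% m$weights[, h])
    Tnew[, h] <- tt
    if (h < ncomp) {
      p_new <- drop(crossprod(Xs, tt)) / sum(tt^2)
      Xs <- Xs - tcrossprod(tt, p_new)
    }
  }
  Yhat <- Tnew %*% t(m$y_loadings[, seq_len(ncomp), drop = FALSE])
  Yhat <- sweep(Yhat, 2, m$y_center, "+")
  colnames(Yhat) <- m$levels
  cls <- switch(distance,
    max = apply(Yhat, 1, which.max),
    centroid = {
      cent <- apply(m$scores[, seq_len(ncomp), drop = FALSE], 2,
                    function(col) tapply(col, m$y, mean))
      cent <- matrix(cent, nrow = length(m$levels))
      d2 <- outer(rowSums(Tnew^2), rowSums(cent^2), "+") - 2 * Tnew %*% t(cent)
      apply(d2, 1, which.min)
    })
  list(class = factor(m$levels[cls], levels = m$levels),
       scores = Yhat, projection = Tnew)
}

#' Leave-one-study-out cross-validation of a MINT model
#'
#' Each study in turn is held out, the model refitted on the remaining
#' studies, and the held-out study (standardized with its own statistics)
#' predicted. Pooled predictions give per-component overall, per-class
#' and balanced error rates; per-held-out-study BERs feed [tune_keepx()].
#'
#' @inheritParams fit_mint_plsda
#' @param distance prediction distance.
#' @return a `PerfResult` with `error`, `ber`, `per_class` (components x
#'   classes), `per_study_ber` (components x studies), and
#'   `pred_scores` (list, per component, of pooled per-class predicted
#'   score matrices aligned with `truth`).
#' @export
logocv_perf <- function(coll, ncomp = 2L, keepX = NULL,
                        genes = coll$shared_genes, distance = "max",
                        scale = TRUE) {
  stopifnot(inherits(coll, "StudyCollection"))
  ids <- names(coll$studies)
  if (length(ids) < 2L) stopf("leave-one-study-out needs >= 2 studies")
  blocks_all <- mint_blocks(coll, genes, scale)
  genes <- colnames(blocks_all[[1]]$X)
  truth <- factor(unlist(lapply(blocks_all, function(b) as.character(b$y))))
  lev <- levels(truth)
  study_of <- rep(ids, vapply(blocks_all, function(b) nrow(b$X), integer(1)))
  n <- length(truth)
  pred <- matrix(NA_character_, n, ncomp)
  scores <- lapply(seq_len(ncomp), function(h)
    matrix(NA_real_, n, length(lev), dimnames = list(NULL, lev)))
  for (held in ids) {
    sub <- coll
    sub$studies <- coll$studies[setdiff(ids, held)]
    sub$study_vector <- droplevels(coll$study_vector[coll$study_vector != held])
    m <- fit_mint_plsda(sub, ncomp = ncomp, keepX = keepX, genes = genes,
                        scale = scale)
    ## raw (unscaled) held-out block on the model's panel
    s <- coll$studies[[held]]
    canon <- map_gene_ids(s$gene_ids, coll$ortholog_map)
    M <- study_log_matrix(s); rownames(M) <- canon
    Xnew <- t(M[genes, , drop = FALSE])
    rows <- which(study_of == held)
    for (h in seq_len(ncomp)) {
      pr <- predict_mint(m, Xnew, distance = distance, ncomp = h)
      pred[rows, h] <- as.character(pr$class)
      sc <- matrix(NA_real_, length(rows), length(lev), dimnames = list(NULL, lev))
      sc[, colnames(pr$scores)] <- pr$scores
      scores[[h]][rows, ] <- sc
    }
  }
  per_class <- matrix(NA_real_, ncomp, length(lev), dimnames = list(NULL, lev))
  per_study <- matrix(NA_real_, ncomp, length(ids), dimnames = list(NULL, ids))
  err <- bal <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    cm <- table(factor(truth, lev), factor(pred[, h], lev))
    err[h] <- 1 - sum(diag(cm)) / n
    per_class[h, ] <- 1 - diag(cm) / rowSums(cm)
    bal[h] <- ber(cm)
    for (id in ids) {
      sel <- study_of == id
      per_study[h, id] <- ber(table(factor(truth[sel], lev),
                                    factor(pred[sel, h], lev)))
    }
  }
  structure(list(error = err, ber = bal, per_class = per_class,
                 per_study_ber = per_study, pred = pred, truth = truth,
                 study_of = study_of, pred_scores = scores,
                 distance = distance, ncomp = ncomp),
            class = "PerfResult")
}

#' Tune the keepX sparsity of a MINT sparse PLS-DA model
#'
#' Evaluates each candidate `keepX` by leave-one-study-out BER; the best
#' value minimizes the mean BER across held-out studies, and the chosen
#' value is the smallest candidate whose per-study BERs are not
#' significantly worse than the best (one-sided paired t-test at
#' `alpha`). Identical BER vectors are treated as comparable.
#'
#' @inheritParams logocv_perf
#' @param grid candidate keepX values (each `<=` panel size).
#' @param ncomp component count at which BER is assessed (default 1).
#' @param alpha t-test significance level.
#' @return a `TuneResult`: `grid`, `per_study_ber` (studies x grid),
#'   `mean_ber`, `best_keepx`, `choice` (chosen keepX), `p_values`.
#' @export
tune_keepx <- function(coll, grid, ncomp = 1L, genes = coll$shared_genes,
                       distance = "max", alpha = 0.05, scale = TRUE) {
  if (!length(grid)) stopf("empty keepX grid")
  if (length(coll$studies) < 2L) stopf("tuning needs >= 2 studies")
  grid <- sort(unique(as.integer(grid)))
  panel <- length(intersect(genes, coll$shared_genes))
  if (any(grid > panel)) {
    stopf("keepX grid value(s) exceed the panel size (%d)", panel)
  }
  bers <- sapply(grid, function(kx) {
    logocv_perf(coll, ncomp = ncomp, keepX = kx, genes = genes,
                distance = distance, scale = scale)$per_study_ber[ncomp, ]
  })
  colnames(bers) <- as.character(grid)
  mean_ber <- colMeans(bers)
  best <- grid[which.min(mean_ber)]
  pv <- vapply(seq_along(grid), function(i) {
    d <- bers[, i] - bers[, as.character(best)]
    if (all(abs(d) < 1e-12)) return(1)
    unname(stats::t.test(d, alternative = "greater")$p.value)
  }, numeric(1))
  comparable <- grid[pv > alpha]
  choice <- if (length(comparable)) min(comparable) else best
  structure(list(grid = grid, per_study_ber = bers, mean_ber = mean_ber,
                 best_keepx = best, choice = choice,
                 p_values = stats::setNames(pv, grid), alpha = alpha),
            class = "TuneResult")
}

#' ROC curve and AUC from class scores
#'
#' Threshold sweep over the predicted scores for the positive class;
#' the AUC equals the tie-corrected Mann-Whitney estimate
#' `U / (n_pos * n_neg)`.
#'
#' @param scores per-sample numeric score for the positive class.
#' @param labels per-sample class labels.
#' @param positive label treated as positive (default: last level).
#' @return a `ROCResult`: `points` (data frame of `fpr`, `tpr`), `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2L) stopf("exactly two classes are required")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  ## Mann-Whitney with midranks (tie correction)
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## monotone curve via threshold sweep at unique score values
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[!pos] >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(points = pts, auc = auc, positive = positive),
            class = "ROCResult")
}

#' Global and per-study sample coordinates of a MINT model
#'
#' @param m a fitted `MINTModel`.
#' @return list with `global` (all samples x components) and
#'   `per_study` (named list of partial score matrices).
#' @export
study_projections <- function(m) {
  stopifnot(inherits(m, "MINTModel"))
  list(global = m$scores, per_study = m$partial_scores)
}
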