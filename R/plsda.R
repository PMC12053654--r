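## PLS-DA core: NIPALS PLS2 on a dummy-coded response, VIP scoring,
## class prediction, cross-validated error rates and the permutation
## validation test. The same NIPALS engine, with an optional per-component
## cardinality constraint on the X-weights, also powers the sparse and
## multi-study variants.

## ---- internal NIPALS engine -------------------------------------------

## Soft-threshold an unnormalized weight vector so exactly keepX entries
## are nonzero (lasso surrogate used by sparse PLS): shrink magnitudes by
## the (keepX+1)-th largest; ties at the threshold keep a sign-preserving
## epsilon so the cardinality contract holds exactly.
soft_threshold_keepx <- function(w, keepX) {
  p <- length(w)
  if (keepX >= p) return(w)
  ord <- order(abs(w), decreasing = TRUE)
  lambda <- abs(w)[ord[keepX + 1L]]
  out <- numeric(p)
  keep <- ord[seq_len(keepX)]
  out[keep] <- sign(w[keep]) * pmax(abs(w[keep]) - lambda, .Machine$double.eps)
  out
}

## NIPALS PLS2 with X- and Y-deflation on pre-centered/scaled matrices.
## keepX: integer per component (p = dense).
nipals_pls <- function(X, Y, ncomp, keepX = rep(ncol(X), ncomp),
                       tol = 1e-14, max_iter = 1000L) {
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, k, ncomp); Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp); ssx <- numeric(ncomp)
  ssx_tot <- sum(X^2); ssy_tot <- sum(Y^2)
  for (h in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2)), drop = TRUE]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      w <- soft_threshold_keepx(w, keepX[h])
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) stopf("degenerate component %d: zero weight vector", h)
      w <- w / nw
      tt <- drop(X %*% w)
      q <- drop(crossprod(Y, tt)) / sum(tt^2)
      u <- drop(Y %*% q) / sum(q^2)
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    pl <- drop(crossprod(X, tt)) / sum(tt^2)
    W[, h] <- w; P[, h] <- pl; Q[, h] <- q; Tm[, h] <- tt
    ssx[h] <- sum(tt^2) * sum(pl^2)
    ssy[h] <- sum(tt^2) * sum(q^2)
    X <- X - tcrossprod(tt, pl)
    Y <- Y - tcrossprod(tt, q)
  }
  list(W = W, P = P, Q = Q, T = Tm,
       expl_x = ssx / ssx_tot, ssy = ssy, expl_y = ssy / ssy_tot)
}

dummy_code <- function(y) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stopf("need >= 2 classes")
  if (any(tabulate(y) < 1L)) stopf("every class needs at least one sample")
  Y <- stats::model.matrix(~ 0 + y)
  colnames(Y) <- levels(y)
  list(Y = Y, levels = levels(y), y = y)
}

center_scale <- function(M, scale = TRUE, what = "X") {
  ctr <- colMeans(M)
  scl <- if (scale) apply(M, 2, stats::sd) else rep(1, ncol(M))
  if (any(scl == 0)) {
    bad <- which(scl == 0)
    stopf("constant %s column(s) cannot be scaled: %s", what,
          paste(utils::head(colnames(M)[bad] %||% bad, 5L), collapse = ", "))
  }
  list(M = sweep(sweep(M, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

## ---- user-facing fits --------------------------------------------------

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis: iterative (NIPALS) PLS2
#' regression of the dummy-coded class membership on the expression
#' matrix, with X-deflation per component. Columns of X and of the dummy
#' response are centered and (by default) scaled to unit variance.
#'
#' @param X samples x genes numeric matrix.
#' @param y per-sample class labels (>= 2 classes).
#' @param ncomp number of components (`<= min(n - 1, p)`).
#' @param scale scale columns to unit variance (default TRUE).
#' @param keepX optional integer vector (recycled to `ncomp`) of
#'   per-component nonzero-weight counts for sparse fits; default dense.
#' @return a `PLSModel`: unit-norm X-weights `weights` (p x ncomp,
#'   mixOmics-style "loadings"), projection loadings `loadings_proj`,
#'   Y-loadings `y_loadings`, scores `scores` (n x ncomp), centering and
#'   scaling vectors, class `levels`, per-component explained variance of
#'   X (`expl_x`) and Y (`expl_y`, with raw `ssy` used by [vip()]).
#' @export
fit_plsda <- function(X, y, ncomp = 2L, scale = TRUE, keepX = NULL) {
  X <- as.matrix(X)
  dc <- dummy_code(y)
  if (length(dc$y) != nrow(X)) stopf("y length != number of samples")
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(n - 1L, p)) {
    stopf("ncomp = %d exceeds min(n - 1, p) = %d", ncomp, min(n - 1L, p))
  }
  keepX <- if (is.null(keepX)) rep(p, ncomp) else rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1L) || any(keepX > p)) stopf("keepX must lie in [1, %d]", p)
  xs <- center_scale(X, scale, "X")
  ys <- center_scale(dc$Y, scale, "Y")
  fit <- nipals_pls(xs$M, ys$M, ncomp, keepX)
  rownames(fit$W) <- rownames(fit$P) <- colnames(X)
  rownames(fit$Q) <- dc$levels
  structure(list(
    weights = fit$W, loadings_proj = fit$P, y_loadings = fit$Q,
    scores = fit$T, ncomp = ncomp, keepX = keepX,
    x_center = xs$center, x_scale = xs$scale,
    y_center = ys$center, y_scale = ys$scale,
    levels = dc$levels, y = dc$y, scale = scale,
    expl_x = fit$expl_x, expl_y = fit$expl_y, ssy = fit$ssy,
    gene_ids = colnames(X)
  ), class = "PLSModel")
}

#' @export
print.PLSModel <- function(x, ...) {
  cat(sprintf("PLSModel: %d components, %d variables, classes: %s\n",
              x$ncomp, nrow(x$weights), paste(x$levels, collapse = "/")))
  if (any(x$keepX < nrow(x$weights))) {
    cat("  sparse keepX:", paste(x$keepX, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Per-variable summary of contribution across PLS components:
#' `VIP_j = sqrt(p * sum_h SS_h * w_jh^2 / sum_h SS_h)` where `SS_h` is
#' the Y-variance explained by component `h` and the weight vectors have
#' unit norm; the mean squared VIP equals 1 by construction.
#'
#' @param m a fitted `PLSModel`.
#' @param ncomp number of components to accumulate (default all).
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(m, ncomp = m$ncomp) {
  stopifnot(inherits(m, "PLSModel"))
  h <- seq_len(ncomp)
  ssy <- m$ssy[h]
  if (sum(ssy) <= 0) stopf("zero explained Y-variance; VIP undefined")
  p <- nrow(m$weights)
  v <- sqrt(p * drop(m$weights[, h, drop = FALSE]^2 %*% ssy) / sum(ssy))
  stats::setNames(v, rownames(m$weights))
}

#' Select variables by VIP threshold
#'
#' @param v named VIP vector from [vip()].
#' @param threshold selection threshold (default 1.5); the boundary is
#'   inclusive (`VIP >= threshold`) unless `strict = TRUE`.
#' @param strict use a strict `>` rule.
#' @return character vector of selected variable names, in decreasing
#'   VIP order.
#' @export
select_by_vip <- function(v, threshold = 1.5, strict = FALSE) {
  keep <- if (strict) v > threshold else v >= threshold
  names(sort(v[keep], decreasing = TRUE))
}

#' Collapse duplicate probes to unique gene symbols
#'
#' When several probes map to the same symbol, the probe with the
#' largest absolute VIP represents the symbol.
#'
#' @param v named per-probe VIP vector.
#' @param symbols per-probe gene symbols (same length as `v`).
#' @return named VIP vector with one entry per unique symbol.
#' @export
collapse_probes_by_vip <- function(v, symbols) {
  if (length(v) != length(symbols)) stopf("v and symbols differ in length")
  ord <- order(abs(v), decreasing = TRUE)
  keep <- ord[!duplicated(symbols[ord])]
  stats::setNames(v[keep], symbols[keep])
}

#' Predict class membership from a PLS-DA model
#'
#' New samples are centered/scaled with the training statistics and
#' projected through the model rotation. `"max"` distance assigns the
#' class with the largest predicted dummy score; `"centroid"` assigns
#' the nearest training class centroid in score space. Ties break to the
#' lowest class index.
#'
#' @param m a fitted `PLSModel`.
#' @param Xnew samples x genes matrix over the model's gene panel.
#' @param distance `"max"` or `"centroid"`.
#' @param ncomp number of components used (default all).
#' @return list with `class` (factor), `scores` (predicted per-class
#'   dummy values), and `projection` (new sample scores).
#' @export
predict_classes <- function(m, Xnew, distance = c("max", "centroid"),
                            ncomp = m$ncomp) {
  stopifnot(inherits(m, "PLSModel"))
  distance <- match.arg(distance)
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != nrow(m$weights)) {
    stopf("Xnew has %d variables; model expects %d", ncol(Xnew), nrow(m$weights))
  }
  if (!is.null(colnames(Xnew)) && !identical(colnames(Xnew), m$gene_ids)) {
    if (!setequal(colnames(Xnew), m$gene_ids)) stopf("gene panel mismatch")
    Xnew <- Xnew[, m$gene_ids, drop = FALSE]
  }
  Xs <- sweep(sweep(Xnew, 2, m$x_center), 2, m$x_scale, "/")
  h <- seq_len(ncomp)
  R <- m$weights[, h, drop = FALSE] %*%
    solve(crossprod(m$loadings_proj[, h, drop = FALSE], m$weights[, h, drop = FALSE]))
  Tnew <- Xs %*% R
  Ys <- Tnew %*% t(m$y_loadings[, h, drop = FALSE])
  Yhat <- sweep(sweep(Ys, 2, m$y_scale, "*"), 2, m$y_center, "+")
  colnames(Yhat) <- m$levels
  cls <- switch(distance,
    max = apply(Yhat, 1, which.max),
    centroid = {
      cent <- apply(m$scores[, h, drop = FALSE], 2,
                    function(col) tapply(col, m$y, mean))
      cent <- matrix(cent, nrow = length(m$levels))
      d2 <- outer(rowSums(Tnew^2), rowSums(cent^2), "+") -
        2 * Tnew %*% t(cent)
      apply(d2, 1, which.min)
    })
  list(class = factor(m$levels[cls], levels = m$levels),
       scores = Yhat, projection = Tnew)
}

## ---- error rates, CV, permutation test --------------------------------

#' Balanced error rate from a confusion matrix
#'
#' @param confusion square matrix of counts, rows = true class, columns
#'   = predicted class.
#' @return the unweighted mean of per-class error rates (classes absent
#'   from the truth are skipped).
#' @export
ber <- function(confusion) {
  confusion <- as.matrix(confusion)
  n_true <- rowSums(confusion)
  present <- n_true > 0
  per_class <- 1 - diag(confusion)[present] / n_true[present]
  mean(per_class)
}

## Stratified fold assignment: within each class, shuffled indices are
## dealt round-robin so every fold keeps near-proportional class counts.
stratified_folds <- function(y, folds, seed = NULL) {
  y <- factor(y)
  with_seed(seed, {
    out <- integer(length(y))
    ## classes processed in first-occurrence order so the assignment is
    ## invariant to relabelling
    for (lv in unique(as.character(y))) {
      idx <- sample(which(y == lv))
      out[idx] <- rep_len(seq_len(folds), length(idx))
    }
    out
  })
}

#' Cross-validated PLS-DA error rates
#'
#' Stratified k-fold (or leave-one-out) cross-validation: the model is
#' refitted on each training split and the held-out samples predicted at
#' every component count.
#'
#' @param X samples x genes matrix.
#' @param y class labels.
#' @param ncomp maximum components.
#' @param folds number of folds, or `"loo"`.
#' @param seed seed for the fold assignment.
#' @param distance prediction distance (see [predict_classes()]).
#' @param scale scale columns (see [fit_plsda()]).
#' @param fold_id optional explicit fold assignment (overrides `folds`).
#' @return a `PerfResult`: per-component `error` (overall), `ber`,
#'   `per_class` (components x classes), `distance`, `fold_id`.
#' @export
cv_error <- function(X, y, ncomp = 2L, folds = 5L, seed = NULL,
                     distance = "max", scale = TRUE, fold_id = NULL) {
  X <- as.matrix(X); y <- droplevels(factor(y))
  n <- nrow(X)
  if (is.null(fold_id)) {
    if (identical(folds, "loo")) {
      fold_id <- seq_len(n)
    } else {
      if (folds < 2L) stopf("folds must be >= 2 (or 'loo')")
      fold_id <- stratified_folds(y, folds, seed)
    }
  }
  pred <- matrix(NA_character_, n, ncomp)
  for (f in unique(fold_id)) {
    test <- fold_id == f
    ytr <- droplevels(y[!test])
    if (nlevels(ytr) < nlevels(y)) {
      stopf("fold %s removes an entire class from training", f)
    }
    m <- fit_plsda(X[!test, , drop = FALSE], ytr, ncomp = ncomp, scale = scale)
    for (h in seq_len(ncomp)) {
      pred[test, h] <- as.character(
        predict_classes(m, X[test, , drop = FALSE], distance, ncomp = h)$class)
    }
  }
  lev <- levels(y)
  per_class <- matrix(NA_real_, ncomp, length(lev),
                      dimnames = list(NULL, lev))
  err <- bal <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    cm <- table(factor(y, lev), factor(pred[, h], lev))
    err[h] <- 1 - sum(diag(cm)) / n
    per_class[h, ] <- 1 - diag(cm) / rowSums(cm)
    bal[h] <- ber(cm)
  }
  structure(list(error = err, ber = bal, per_class = per_class,
                 distance = distance, fold_id = fold_id, ncomp = ncomp),
            class = "PerfResult")
}

#' Permutation validation of a PLS-DA model
#'
#' Class labels are randomly permuted `B` times; the cross-validated
#' error rate of each permuted model (with the fold scheme held fixed) is
#' compared to the true model's error. The empirical p-value is
#' `(1 + #\{null <= true\}) / (B + 1)`.
#'
#' @inheritParams cv_error
#' @param B number of permutations (default 500).
#' @param seed seed governing folds and permutations.
#' @param folds number of folds; with fewer than 15 samples leave-one-out
#'   is used instead.
#' @return a `PermutationResult`: `true_error`, `null_errors` (length
#'   `B`), `empirical_p`.
#' @export
permutation_test <- function(X, y, ncomp = 1L, B = 500L, seed = 1L,
                             folds = 5L, distance = "max", scale = TRUE) {
  if (B < 1L) stopf("B must be >= 1")
  X <- as.matrix(X); y <- droplevels(factor(y))
  n <- nrow(X)
  fold_id <- if (n < 15L) seq_len(n) else stratified_folds(y, folds, seed)
  true_err <- cv_error(X, y, ncomp, fold_id = fold_id, distance = distance,
                       scale = scale)$error[ncomp]
  null_errors <- with_seed(seed + 1L, {
    vapply(seq_len(B), function(b) {
      yp <- sample(y)
      cv_error(X, yp, ncomp, fold_id = fold_id, distance = distance,
               scale = scale)$error[ncomp]
    }, numeric(1))
  })
  structure(list(true_error = true_err, null_errors = null_errors,
                 empirical_p = (1 + sum(null_errors <= true_err)) / (B + 1)),
            class = "PermutationResult")
}

## ---- PCA and plotting geometry ----------------------------------------

#' Principal component analysis
#'
#' SVD-based PCA with a fixed sign convention: within each component the
#' loading entry of largest magnitude is positive.
#'
#' @param X samples x genes matrix.
#' @param center,scale passed to [stats::prcomp()].
#' @param ncomp number of components returned (default all).
#' @return list with `scores`, `loadings`, `explained` (fractions over
#'   all components, summing to 1), `sdev`.
#' @export
pca <- function(X, center = TRUE, scale = TRUE, ncomp = NULL) {
  X <- as.matrix(X)
  if (scale && any(apply(X, 2, stats::sd) == 0)) {
    stopf("constant column(s) cannot be scaled")
  }
  pc <- stats::prcomp(X, center = center, scale. = scale)
  if (is.null(ncomp)) ncomp <- ncol(pc$rotation)
  ncomp <- min(ncomp, ncol(pc$rotation))
  flip <- vapply(seq_len(ncomp), function(h) {
    v <- pc$rotation[, h]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(ncomp), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(ncomp), drop = FALSE], 2, flip, "*")
  list(scores = scores, loadings = loadings,
       explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}

#' Gaussian confidence ellipse of a 2-D point cloud
#'
#' Ellipse from the sample mean and covariance, with axes scaled by the
#' chi-square(2) quantile at `level` (95% by default).
#'
#' @param points n x 2 matrix (>= 3 points).
#' @param level coverage level.
#' @return list with `center`, `semi_axes` (lengths, decreasing),
#'   `angle` (radians, first axis vs. x), `radius`
#'   (`sqrt(qchisq(level, 2))`).
#' @export
group_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 2L) stopf("need >= 3 points in 2 dimensions")
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values)) stopf("singular covariance")
  r <- sqrt(stats::qchisq(level, df = 2))
  list(center = colMeans(points),
       semi_axes = sqrt(ev$values) * r,
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       radius = r)
}
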