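test_that("PCA equals a direct SVD oracle with the fixed sign convention", {
  set.seed(21)
  X <- matrix(rnorm(60), 10, 6)
  res <- pca(X, center = TRUE, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc)
  for (h in 1:6) {
    s_or <- sv$u[, h] * sv$d[h]
    agree <- min(max(abs(res$scores[, h] - s_or)), max(abs(res$scores[, h] + s_or)))
    expect_lt(agree, 1e-10)
  }
  expect_equal(sum(res$explained), 1, tolerance = 1e-12)
  ## sign convention: largest-|loading| entry positive
  for (h in 1:6) {
    v <- res$loadings[, h]
    expect_gt(v[which.max(abs(v))], 0)
  }
  ## rank-1 data: PC1 explains everything
  r1 <- tcrossprod(rnorm(8), rnorm(5))
  res1 <- pca(r1, scale = FALSE)
  expect_equal(res1$explained[1], 1, tolerance = 1e-10)
  expect_error(pca(cbind(X, 1)), "constant")
})

test_that("PLS-DA weights solve the PLS criterion and scores are orthogonal", {
  set.seed(22)
  X <- matrix(rnorm(40), 8, 5)
  y <- rep(c("a", "b"), each = 4)
  m <- fit_plsda(X, y, ncomp = 3)
  ## component-1 weights: dominant eigenvector of X' Y Y' X on the
  ## centered/scaled matrices (brute-force eigendecomposition)
  Xs <- scale(X)
  Ys <- scale(model.matrix(~ 0 + factor(y)))
  ev <- eigen(t(Xs) %*% Ys %*% t(Ys) %*% Xs, symmetric = TRUE)$vectors[, 1]
  agree <- min(max(abs(m$weights[, 1] - ev)), max(abs(m$weights[, 1] + ev)))
  expect_lt(agree, 1e-8)
  ## unit-norm weights and orthogonal scores
  expect_equal(colSums(m$weights^2), rep(1, 3), tolerance = 1e-10)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("a single informative coordinate takes the whole first weight vector", {
  ## all other columns are exactly orthogonal to the class contrast
  y <- rep(c("a", "b"), each = 4)
  base <- c(1, -1, 1, -1, 1, -1, 1, -1)   # zero covariance with the contrast
  X <- cbind(info = c(0, 0, 0, 0, 1, 1, 1, 1), n1 = base, n2 = rev(base) * 2)
  m <- fit_plsda(X, y, ncomp = 1)
  expect_equal(unname(abs(m$weights["info", 1])), 1, tolerance = 1e-10)
  expect_equal(unname(abs(m$weights[c("n1", "n2"), 1])), c(0, 0), tolerance = 1e-10)
})

test_that("VIP obeys its closed forms and normalization", {
  tc <- toy_classed_matrix()
  m <- fit_plsda(tc$X, tc$y, ncomp = 2)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_true(all(v >= 0))
  ## ncomp = 1: VIP = sqrt(p) |w|
  v1 <- vip(m, ncomp = 1)
  expect_equal(unname(v1), sqrt(ncol(tc$X)) * abs(unname(m$weights[, 1])),
               tolerance = 1e-10)
  ## p = 1: VIP forced to 1
  m1 <- fit_plsda(matrix(c(tc$X[, 1]), ncol = 1), tc$y, ncomp = 1)
  expect_equal(unname(vip(m1)), 1, tolerance = 1e-10)
  ## two-variable single-component model: VIP = sqrt(2) * |w|
  m2 <- fit_plsda(tc$X[, 1:2], tc$y, ncomp = 1)
  expect_equal(unname(vip(m2)), sqrt(2) * abs(unname(m2$weights[, 1])),
               tolerance = 1e-10)
})

test_that("VIP and weights agree with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  tc <- toy_classed_matrix(n_per = 15L, p = 10L, seed = 33L)
  m <- fit_plsda(tc$X, tc$y, ncomp = 2)
  mo <- mixOmics::plsda(tc$X, tc$y, ncomp = 2)
  for (h in 1:2) {
    agree <- min(max(abs(m$weights[, h] - mo$loadings$X[, h])),
                 max(abs(m$weights[, h] + mo$loadings$X[, h])))
    expect_lt(agree, 1e-6)
  }
  expect_equal(unname(vip(m)), unname(mixOmics::vip(mo)[, 2]), tolerance = 1e-6)
})

test_that("VIP selection is inclusive at the threshold and ordered", {
  v <- c(g1 = 2.0, g2 = 1.5, g3 = 0.3)
  expect_equal(select_by_vip(v), c("g1", "g2"))
  expect_equal(select_by_vip(v, strict = TRUE), "g1")
  expect_equal(collapse_probes_by_vip(c(p1 = 1.2, p2 = 1.9, p3 = 0.1),
                                      c("A", "A", "B")),
               c(A = 1.9, B = 0.1))
})

test_that("class prediction follows argmax / nearest-centroid with deterministic ties", {
  tc <- toy_classed_matrix(shift = 4)
  m <- fit_plsda(tc$X, tc$y, ncomp = 2)
  pr <- predict_classes(m, tc$X)
  expect_equal(as.character(pr$class), as.character(tc$y))   # separable
  expect_equal(unname(apply(pr$scores, 1, which.max)),
               as.integer(tc$y))
  ## centroid distance matches an explicit score-space computation
  prc <- predict_classes(m, tc$X, distance = "centroid", ncomp = 1)
  cent <- tapply(m$scores[, 1], tc$y, mean)
  manual <- levels(tc$y)[apply(abs(outer(prc$projection[, 1], cent, "-")), 1, which.min)]
  expect_equal(as.character(prc$class), manual)
  expect_error(predict_classes(m, tc$X[, 1:3]), "variables")
})

test_that("balanced error rate follows its definition", {
  expect_equal(ber(diag(c(5, 7))), 0)
  expect_equal(ber(matrix(c(9, 3, 1, 7), 2, 2)), 0.2)  # errors 0.1 and 0.3
  ## balanced classes: BER equals the overall error for any confusion
  for (i in 1:20) {
    set.seed(i)
    n <- 10
    cm <- matrix(0, 2, 2)
    a <- sample(0:n, 1); b <- sample(0:n, 1)
    cm[1, ] <- c(n - a, a); cm[2, ] <- c(b, n - b)
    expect_equal(ber(cm), 1 - sum(diag(cm)) / sum(cm))
  }
})

test_that("cross-validated error is stratified and label-rename invariant", {
  tc <- toy_classed_matrix(n_per = 12L, shift = 2.5, seed = 55L)
  r1 <- cv_error(tc$X, tc$y, ncomp = 2, folds = 4, seed = 9)
  y2 <- factor(ifelse(tc$y == "lean", "zzz", "aaa"))
  r2 <- cv_error(tc$X, y2, ncomp = 2, folds = 4, seed = 9)
  expect_equal(r1$error, r2$error)
  expect_equal(r1$ber, r2$ber)
  expect_true(all(r1$error >= 0 & r1$error <= 1))
  expect_equal(r1$ber, rowMeans(r1$per_class))
  ## every fold keeps both classes in training
  expect_error(cv_error(tc$X, tc$y, folds = 4,
                        fold_id = ifelse(tc$y == "lean", 1, 2)),
               "entire class")
})

test_that("permutation test separates signal from null and bounds its p-value", {
  set.seed(5)
  X <- matrix(rnorm(24 * 50), 24, 50)
  y <- rep(c("a", "b"), each = 12)
  Xs <- X; Xs[y == "b", 1:10] <- Xs[y == "b", 1:10] + 3
  pt <- permutation_test(Xs, y, ncomp = 1, B = 99, seed = 7)
  expect_equal(pt$true_error, 0)
  expect_equal(pt$empirical_p, 1 / 100)
  expect_true(all(pt$null_errors > 0))
  ## pure noise: p bounded below by 1/(B+1), typically large
  pn <- permutation_test(X, y, ncomp = 1, B = 19, seed = 8)
  expect_gte(pn$empirical_p, 1 / 20)
  expect_lte(pn$empirical_p, 1)
})

test_that("group ellipses come from the chi-square quantile geometry", {
  set.seed(6)
  pts <- matrix(rnorm(400), 200, 2)
  el <- group_ellipse(pts)
  expect_equal(el$radius, sqrt(qchisq(0.95, 2)), tolerance = 1e-12)
  expect_equal(el$radius, 2.4477, tolerance = 1e-4)
  expect_equal(el$center, colMeans(pts))
  ## diagonal covariance (4, 1): semi-axis ratio 2
  pts2 <- cbind(c(-2, 2, 0, 0, -2, 2), c(0, 0, 1, -1, 1, -1))
  S <- cov(pts2)
  el2 <- group_ellipse(pts2)
  expect_equal(el2$semi_axes[1] / el2$semi_axes[2],
               sqrt(max(eigen(S)$values) / min(eigen(S)$values)),
               tolerance = 1e-10)
  expect_error(group_ellipse(cbind(1:5, 2 * (1:5))), "singular")
})

test_that("planted signatures rank above noise genes by VIP", {
  ## a VIP-threshold selection on the signature-recovery conditions keeps
  ## every planted gene and concentrates them at the top of the ranking
  cfg <- study_config("disc", platform = "microarray",
                      n_per_class = c(lean = 20L, obese = 20L),
                      n_genes = 2000L, seed = 11L)
  set.seed(12)
  sig <- planted_signature(sample(sprintf("GENE%04d", 1:2000), 100), 1.5)
  st <- simulate_microarray_study(cfg, sig)
  M <- st$matrix; rownames(M) <- canonical_gene_id(rownames(M))
  m <- fit_plsda(t(M), st$class_labels, ncomp = 1)
  v <- vip(m)
  sel <- select_by_vip(v, 1.5)
  sens <- length(intersect(sel, sig$gene_ids)) / length(sig$gene_ids)
  expect_gte(sens, 0.8)
  ## rank-biserial separation of planted vs noise VIPs
  planted <- names(v) %in% sig$gene_ids
  auc <- roc_auc(v, factor(ifelse(planted, "sig", "null"), c("null", "sig")),
                 positive = "sig")$auc
  expect_gte(2 * auc - 1, 0.8)
})
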