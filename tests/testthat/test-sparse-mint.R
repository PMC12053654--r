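test_that("sparse fits reduce to dense at keepX = p and keep exact cardinality", {
  tc <- toy_classed_matrix(n_per = 12L, p = 15L, seed = 61L)
  dense <- fit_plsda(tc$X, tc$y, ncomp = 2)
  sp_full <- fit_splsda(tc$X, tc$y, ncomp = 2, keepX = 15)
  expect_lt(max(abs(dense$weights - sp_full$weights)), 1e-8)
  expect_lt(max(abs(dense$scores - sp_full$scores)), 1e-8)
  for (kx in c(1L, 4L, 9L)) {
    sp <- fit_splsda(tc$X, tc$y, ncomp = 2, keepX = kx)
    expect_equal(unname(colSums(sp$weights != 0)), rep(kx, 2))
  }
  expect_error(fit_splsda(tc$X, tc$y, keepX = 99), "keepX")
})

test_that("keepX = 1 retains the variable maximizing covariance with the response", {
  set.seed(62)
  X <- matrix(rnorm(20 * 6), 20, 6); colnames(X) <- paste0("g", 1:6)
  y <- rep(c("a", "b"), each = 10)
  X[y == "b", 4] <- X[y == "b", 4] + 1.5
  sp <- fit_splsda(X, y, ncomp = 1, keepX = 1)
  picked <- rownames(sp$weights)[sp$weights[, 1] != 0]
  ## brute force over variables: largest |covariance| with the scaled dummy
  Xs <- scale(X); Ys <- scale(model.matrix(~ 0 + factor(y)))
  covs <- abs(crossprod(Xs, Ys[, 1]))
  expect_equal(picked, colnames(X)[which.max(covs)])
})

test_that("sparse selection matches mixOmics splsda", {
  skip_if_not_installed("mixOmics")
  tc <- toy_classed_matrix(n_per = 12L, p = 20L, n_signal = 4L, seed = 63L)
  sp <- fit_splsda(tc$X, tc$y, ncomp = 2, keepX = 5)
  mo <- mixOmics::splsda(tc$X, tc$y, ncomp = 2, keepX = c(5, 5))
  sel_mo <- rownames(mo$loadings$X)[mo$loadings$X[, 1] != 0]
  expect_setequal(rownames(sp$weights)[sp$weights[, 1] != 0], sel_mo)
  agree <- min(max(abs(sp$weights[, 1] - mo$loadings$X[, 1])),
               max(abs(sp$weights[, 1] + mo$loadings$X[, 1])))
  expect_lt(agree, 1e-6)
})

test_that("single-study MINT reduces exactly to PLS-DA", {
  pre <- integration_preset(seed = 3, n_genes = 150L, n_planted = 20L)
  coll <- pre$collection
  one <- coll
  one$studies <- coll$studies[1]
  one$study_vector <- droplevels(coll$study_vector[coll$study_vector == names(coll$studies)[1]])
  m1 <- fit_mint_plsda(one, ncomp = 2)
  s <- coll$studies[[1]]
  M <- study_log_matrix(s); rownames(M) <- map_gene_ids(s$gene_ids)
  mp <- fit_plsda(t(M[one$shared_genes, ]), s$class_labels, ncomp = 2)
  expect_lt(max(abs(abs(m1$scores) - abs(mp$scores))), 1e-8)
  expect_lt(max(abs(abs(m1$weights) - abs(mp$weights))), 1e-8)
})

test_that("duplicated studies reproduce the single-study loadings", {
  set.seed(64)
  X <- matrix(rnorm(30 * 40), 40, 30)
  colnames(X) <- sprintf("GENE%04d", 1:30)
  y <- rep(c("lean", "obese"), each = 20)
  X[y == "obese", 1:5] <- X[y == "obese", 1:5] + 2
  mk <- function(id) expression_study(t(X), y, id, "microarray")
  coll <- study_collection(list(mk("s1"), mk("s2")))
  mm <- fit_mint_plsda(coll, ncomp = 2)
  mp <- fit_plsda(X, y, ncomp = 2)
  expect_lt(max(abs(abs(mm$weights) - abs(mp$weights))), 1e-8)
})

test_that("per-study additive offsets leave MINT fits and LOGOCV unchanged", {
  pre <- integration_preset(seed = 5, n_genes = 120L, n_planted = 15L,
                            gene_dropout_rate = 0)
  coll <- pre$collection
  shifted <- coll
  set.seed(65)
  for (i in seq_along(shifted$studies)) {
    if (shifted$studies[[i]]$platform == "microarray") {
      shifted$studies[[i]]$matrix <- shifted$studies[[i]]$matrix +
        rnorm(nrow(shifted$studies[[i]]$matrix), 0, 3)
    }
  }
  m0 <- fit_mint_plsda(coll, ncomp = 2)
  m1 <- fit_mint_plsda(shifted, ncomp = 2)
  expect_lt(max(abs(m0$weights - m1$weights)), 1e-6)
  p0 <- logocv_perf(coll, ncomp = 1)
  p1 <- logocv_perf(shifted, ncomp = 1)
  expect_equal(p0$ber, p1$ber, tolerance = 1e-6)
  a0 <- roc_auc(p0$pred_scores[[1]][, "obese"], p0$truth, positive = "obese")$auc
  a1 <- roc_auc(p1$pred_scores[[1]][, "obese"], p1$truth, positive = "obese")$auc
  expect_equal(a0, a1, tolerance = 1e-6)
})

test_that("sparse MINT recovers a strongly planted small signature", {
  pre <- integration_preset(seed = 6, n_genes = 200L, n_planted = 10L,
                            effect = 2, gene_dropout_rate = 0)
  mm <- fit_mint_splsda(pre$collection, ncomp = 1, keepX = 10)
  sel <- rownames(mm$weights)[mm$weights[, 1] != 0]
  expect_gte(length(intersect(sel, pre$signature$gene_ids)), 8L)
  expect_equal(sum(mm$weights[, 1] != 0), 10L)
  ## keepX = panel size equals the dense fit
  dense <- fit_mint_plsda(pre$collection, ncomp = 1)
  full <- fit_mint_splsda(pre$collection, ncomp = 1,
                          keepX = length(pre$collection$shared_genes))
  expect_lt(max(abs(dense$weights - full$weights)), 1e-10)
})

test_that("study projections partition the global scores", {
  pre <- integration_preset(seed = 7, n_genes = 100L, n_planted = 10L)
  mm <- fit_mint_plsda(pre$collection, ncomp = 2)
  pr <- study_projections(mm)
  expect_equal(do.call(rbind, unname(pr$per_study)), pr$global,
               ignore_attr = TRUE)
  n_per <- vapply(pre$collection$studies, function(s) ncol(s$matrix), integer(1))
  expect_equal(unname(vapply(pr$per_study, nrow, integer(1))), unname(n_per))
})

test_that("LOGOCV is near-perfect on separable data and near chance on null data", {
  pre <- integration_preset(seed = 8, n_genes = 150L, n_planted = 40L, effect = 2)
  perf <- logocv_perf(pre$collection, ncomp = 1)
  expect_lte(perf$ber[1], 0.05)
  expect_equal(perf$ber, rowMeans(perf$per_class))
  np <- null_preset(seed = 8, n_genes = 100L)
  p0 <- logocv_perf(np$collection, ncomp = 1)
  expect_gte(p0$ber[1], 0.35)
  expect_lte(p0$ber[1], 0.65)
  expect_error(logocv_perf(structure(list(studies = pre$collection$studies[1]),
                                     class = "StudyCollection")),
               ">= 2 studies")
})

test_that("keepX tuning picks the sparsest comparable model", {
  pre <- integration_preset(seed = 9, n_genes = 150L, n_planted = 10L,
                            effect = 2, gene_dropout_rate = 0)
  tr <- tune_keepx(pre$collection, grid = c(5, 10, 80), ncomp = 1)
  expect_true(tr$choice %in% tr$grid)
  expect_lte(tr$mean_ber[as.character(tr$choice)] - min(tr$mean_ber), 0.05)
  ## grid of one value: chosen is that value
  tr1 <- tune_keepx(pre$collection, grid = 150, ncomp = 1)
  expect_equal(tr1$choice, 150L)
  expect_error(tune_keepx(pre$collection, grid = integer(0)), "empty")
})

test_that("ROC/AUC equals Mann-Whitney with tie correction", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), factor(c("n", "n", "p", "p"), c("n", "p")))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), factor(c("n", "n", "p", "p")))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), factor(rep(c("n", "p"), 3)))$auc, 0.5)
  ## monotone curve from (0,0) to (1,1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  expect_error(roc_auc(1:3, factor(rep("n", 3), c("n", "p"))), "both classes")
})

test_that("AUC matches the pROC reference on seeded scores", {
  skip_if_not_installed("pROC")
  set.seed(66)
  sc <- rnorm(40)
  lab <- factor(rep(c("n", "p"), 20), c("n", "p"))
  sc[lab == "p"] <- sc[lab == "p"] + 1
  ours <- roc_auc(sc, lab, positive = "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})
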