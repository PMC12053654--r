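test_that("phenotype cohort has the default structure and is deterministic", {
  p <- simulate_phenotypes()
  expect_equal(nrow(p), 27L)
  expect_equal(nlevels(p$latent_class), 3L)
  expect_equal(as.integer(table(p$latent_class)), c(7L, 9L, 11L))
  expect_identical(p, simulate_phenotypes())
  p2 <- simulate_phenotypes(cohort_config(seed = 2L))
  expect_false(identical(p$bw_t0, p2$bw_t0))
  expect_true(all(p$bw_t0 > 0 & p$fat_t0 > 0 & p$lean_t0 > 0))
})

test_that("zero within-class noise with equal deltas gives identical gains", {
  cfg <- cohort_config(within_class_sd_pct = 0,
                       class_delta_bw_pct = c(20, 20, 20),
                       class_delta_fat_pct = c(50, 50, 50))
  p <- derive_body_metrics(simulate_phenotypes(cfg))
  expect_equal(diff(range(p$delta_bw_pct)), 0, tolerance = 1e-10)
  expect_equal(p$delta_bw_pct[1], 20, tolerance = 1e-10)
})

test_that("per-class mean gains match the configured deltas (law of large numbers)", {
  deltas <- c(5, 20, 40)
  cfg <- cohort_config(n_animals = 300L, class_prop = c(1, 1, 1),
                       class_delta_bw_pct = deltas,
                       class_delta_fat_pct = c(10, 50, 100),
                       within_class_sd_pct = 2, seed = 1L)
  p <- derive_body_metrics(simulate_phenotypes(cfg))
  obs <- tapply(p$delta_bw_pct, p$latent_class, mean)
  n_cl <- as.integer(table(p$latent_class))
  expect_true(all(abs(obs - deltas) <= 3 * 2 / sqrt(n_cl)))
})

test_that("cohort config validates its arguments", {
  expect_error(cohort_config(n_animals = 0), "n_animals")
  expect_error(cohort_config(baseline_bw_sd = -1), "baseline_bw_sd")
  expect_error(cohort_config(class_delta_bw_pct = c(1, 2)), "length")
})

test_that("noiseless microarray studies reproduce baseline plus batch shift exactly", {
  cfg <- study_config("a", platform = "microarray", noise_sd = 0,
                      n_per_class = c(lean = 3L, obese = 3L), n_genes = 50L)
  st <- simulate_microarray_study(cfg)
  ## with zero residual noise every sample equals gene baseline + batch
  expect_equal(max(apply(st$matrix, 1, function(r) diff(range(r)))), 0)
  ## the batch component is a per-gene constant: a second config that
  ## differs only in batch sd changes the gene means, not the within-gene
  ## spread
  cfg2 <- study_config("a", platform = "microarray", noise_sd = 0,
                       batch_shift_sd = 2,
                       n_per_class = c(lean = 3L, obese = 3L), n_genes = 50L)
  st2 <- simulate_microarray_study(cfg2)
  expect_equal(max(apply(st2$matrix, 1, function(r) diff(range(r)))), 0)
})

test_that("planted standardized shifts are recovered from generated data", {
  g <- sprintf("GENE%04d", 1:200)
  sig <- planted_signature(g[1:5], effect = 1.5)
  cfg <- study_config("big", platform = "microarray",
                      n_per_class = c(lean = 250L, obese = 250L),
                      n_genes = 200L, seed = 3L)
  st <- simulate_microarray_study(cfg, sig)
  y <- st$class_labels
  M <- st$matrix
  rownames(M) <- canonical_gene_id(rownames(M))
  d_hat <- vapply(g[1:5], function(gene) {
    a <- M[gene, y == "obese"]; b <- M[gene, y == "lean"]
    (mean(a) - mean(b)) / sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                                 (length(a) + length(b) - 2))
  }, numeric(1))
  expect_true(all(abs(d_hat - 1.5) < 0.3))
  ## determinism: same config + signature twice is byte-identical
  expect_identical(st$matrix, simulate_microarray_study(cfg, sig)$matrix)
})

test_that("RNA-seq counts follow the configured NB moments", {
  g <- sprintf("GENE%04d", 1:100)
  sig <- planted_signature(g[1], effect = 2)
  cfg <- study_config("rna", platform = "rnaseq",
                      n_per_class = c(lean = 400L, obese = 400L),
                      n_genes = 100L, nb_dispersion = 0.05,
                      libsize_sd = 0, batch_shift_sd = 0, seed = 5L)
  st <- simulate_rnaseq_study(cfg, sig)
  M <- st$matrix; rownames(M) <- canonical_gene_id(rownames(M))
  y <- st$class_labels
  ratio <- mean(M[g[1], y == "obese"]) / mean(M[g[1], y == "lean"])
  expect_equal(ratio, 4, tolerance = 0.15)
  expect_true(all(M >= 0) && all(M == round(M)))
  ## Poisson limit: dispersion 0 gives variance ~ mean
  cfg0 <- study_config("poi", platform = "rnaseq",
                       n_per_class = c(lean = 500L, obese = 500L),
                       n_genes = 50L, nb_dispersion = 0, libsize_sd = 0,
                       batch_shift_sd = 0, seed = 6L)
  st0 <- simulate_rnaseq_study(cfg0)
  mu <- rowMeans(st0$matrix)
  v <- apply(st0$matrix, 1, var)
  keep <- mu > 50
  expect_true(median(abs(v[keep] / mu[keep] - 1)) < 0.15)
})

test_that("study config rejects invalid parameters", {
  expect_error(study_config("x", nb_dispersion = -1), "nb_dispersion")
  expect_error(study_config("x", gene_dropout_rate = 1), "gene_dropout_rate")
  expect_error(study_config("x", n_per_class = c(lean = 5L)), "two classes")
  expect_error(simulate_rnaseq_study(study_config("x", platform = "microarray")),
               "rnaseq")
})

test_that("multi-study collections track shared genes and planted truth", {
  universe <- sprintf("GENE%04d", 1:300)
  set.seed(9)
  sig <- planted_signature(sample(universe, 30), effect = 1.5)
  cfgs <- lapply(1:3, function(i) {
    study_config(paste0("s", i), platform = "microarray",
                 n_per_class = c(lean = 5L, obese = 5L), n_genes = 300L,
                 gene_dropout_rate = 0.10, seed = i)
  })
  coll <- simulate_multistudy_collection(cfgs, sig)
  ## oracle: brute-force set intersection of the generated panels
  panels <- lapply(coll$studies, function(s) canonical_gene_id(s$gene_ids))
  expect_setequal(coll$shared_genes, Reduce(intersect, panels))
  ## truth bookkeeping: carried = planted restricted to each panel
  for (id in names(coll$studies)) {
    expect_setequal(coll$truth$carried[[id]],
                    intersect(sig$gene_ids, panels[[id]]))
  }
  ## no dropout: shared panel is the full universe
  cfgs0 <- lapply(cfgs, function(cf) { cf$gene_dropout_rate <- 0; cf })
  coll0 <- simulate_multistudy_collection(cfgs0, sig)
  expect_setequal(coll0$shared_genes, universe)
  ## default preset: 7 studies, mouse + human id styles align
  pre <- integration_preset(seed = 1, n_genes = 120L, n_planted = 10L)
  expect_length(pre$collection$studies, 7L)
  expect_true(length(pre$collection$shared_genes) < 120L)
})
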