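## Small seeded fixtures shared across test files. Everything is built
## in code; nothing is read from disk.

## tiny two-class sample x gene matrix with a shift on the first genes
toy_classed_matrix <- function(n_per = 10L, p = 12L, n_signal = 3L,
                               shift = 2, seed = 42L) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  colnames(X) <- sprintf("g%02d", seq_len(p))
  y <- factor(rep(c("lean", "obese"), each = n_per))
  X[y == "obese", seq_len(n_signal)] <- X[y == "obese", seq_len(n_signal)] + shift
  list(X = X, y = y)
}

## small count matrix with controllable library sizes
toy_counts <- function(p = 20L, n = 4L, seed = 7L, libsize = 5e4) {
  set.seed(seed)
  ab <- rexp(p); ab <- ab / sum(ab)
  counts <- sapply(seq_len(n), function(s) rpois(p, ab * libsize))
  rownames(counts) <- sprintf("g%02d", seq_len(p))
  colnames(counts) <- sprintf("s%d", seq_len(n))
  counts
}

## three-class discovery study + matching two-class collection sharing
## one planted signature (mini version of the full design)
mini_design <- function(seed = 1L, n_genes = 500L, n_planted = 40L,
                        effect = 1.5, n_per_class_disc = 20L) {
  universe <- sprintf("GENE%04d", seq_len(n_genes))
  set.seed(seed + 99L)
  sig <- planted_signature(sample(universe, n_planted), effect = effect)
  disc_classes <- list(c(R = n_per_class_disc, I = n_per_class_disc, P = n_per_class_disc),
                       c(R = n_per_class_disc, I = n_per_class_disc, P = n_per_class_disc),
                       c(A = 12L, B = 10L, D = 8L))
  plats <- c("microarray", "microarray", "rnaseq")
  disc <- lapply(1:3, function(i) {
    cfg <- study_config(paste0("disc", i), platform = plats[i],
                        n_per_class = disc_classes[[i]], n_genes = n_genes,
                        seed = seed + 10L * i)
    simulate_study(cfg, sig)
  })
  names(disc) <- vapply(disc, `[[`, character(1), "study_id")
  int_cfgs <- lapply(1:4, function(i) {
    study_config(paste0("int", i),
                 platform = if (i == 3) "rnaseq" else "microarray",
                 n_per_class = c(lean = 9L, obese = 11L), n_genes = n_genes,
                 gene_dropout_rate = 0.05,
                 species = if (i <= 2) "mouse" else "human",
                 seed = seed + 1000L * i)
  })
  coll <- simulate_multistudy_collection(int_cfgs, sig)
  list(discovery = disc, collection = coll, signature = sig)
}
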