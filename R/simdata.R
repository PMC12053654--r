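## Synthetic phenotype cohorts and multi-study expression data with a
## planted discriminative gene set. The generators emulate the structure
## of the experimental design the package targets: an inbred mouse cohort
## phenotyped before and after a high-fat-diet challenge, and a set of
## two-class (lean vs. obese) transcriptome studies on mixed microarray /
## RNA-seq platforms with study-level batch effects and per-study
## gene-panel dropout.

#' Configuration for a synthetic phenotyped cohort
#'
#' Defaults emulate an inbred cohort of 27 adult mice split into three
#' latent diet-induced-obesity sensitivity classes (resistant /
#' intermediate / prone) with class sizes 7/9/11.
#'
#' @param n_animals number of animals.
#' @param n_classes number of latent sensitivity classes.
#' @param class_prop relative class sizes (length `n_classes`).
#' @param baseline_bw_mean,baseline_bw_sd body weight at T0, grams.
#' @param class_delta_bw_pct per-class mean percent body-weight gain over
#'   the challenge (length `n_classes`).
#' @param class_delta_fat_pct per-class mean percent fat-mass gain.
#' @param within_class_sd_pct within-class SD of the percent gains.
#' @param fat_fraction_mean,fat_fraction_sd baseline fat mass as a
#'   fraction of body weight.
#' @param seed integer seed.
#' @return a `CohortConfig` list.
#' @export
cohort_config <- function(n_animals = 27L, n_classes = 3L,
                          class_prop = c(7, 9, 11),
                          baseline_bw_mean = 28, baseline_bw_sd = 1.5,
                          class_delta_bw_pct = c(8, 25, 45),
                          class_delta_fat_pct = c(40, 130, 260),
                          within_class_sd_pct = 5,
                          fat_fraction_mean = 0.12, fat_fraction_sd = 0.015,
                          seed = 1L) {
  check_number(n_animals, "n_animals", lower = 1)
  check_number(n_classes, "n_classes", lower = 1)
  if (length(class_delta_bw_pct) != n_classes ||
      length(class_delta_fat_pct) != n_classes) {
    stopf("class delta lists must have length n_classes = %d", n_classes)
  }
  if (length(class_prop) != n_classes) stopf("class_prop must have length n_classes")
  check_number(baseline_bw_sd, "baseline_bw_sd", lower = 0)
  check_number(within_class_sd_pct, "within_class_sd_pct", lower = 0)
  check_number(fat_fraction_sd, "fat_fraction_sd", lower = 0)
  structure(list(
    n_animals = as.integer(n_animals), n_classes = as.integer(n_classes),
    class_prop = class_prop / sum(class_prop),
    baseline_bw_mean = baseline_bw_mean, baseline_bw_sd = baseline_bw_sd,
    class_delta_bw_pct = class_delta_bw_pct,
    class_delta_fat_pct = class_delta_fat_pct,
    within_class_sd_pct = within_class_sd_pct,
    fat_fraction_mean = fat_fraction_mean, fat_fraction_sd = fat_fraction_sd,
    seed = as.integer(seed)
  ), class = "CohortConfig")
}

#' Simulate a phenotyped cohort
#'
#' Draws baseline body composition, assigns each animal to a latent
#' sensitivity class, and applies class-specific percent gains in body
#' weight and fat mass over the challenge period. Lean mass is the
#' remainder of body weight after fat.
#'
#' @param config a [cohort_config()].
#' @return a data frame (one row per animal) with columns `animal_id`,
#'   `latent_class` (ground truth), `bw_t0`, `bw_t18`, `fat_t0`,
#'   `fat_t18`, `lean_t0`, `lean_t18` (grams).
#' @export
simulate_phenotypes <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$n_animals
  with_seed(config$seed, {
    ## deterministic class sizes: largest-remainder apportionment
    sizes <- floor(config$class_prop * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac <- config$class_prop * n - sizes
      sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <- sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    cls <- rep(seq_len(config$n_classes), sizes)
    bw0 <- pmax(1, stats::rnorm(n, config$baseline_bw_mean, config$baseline_bw_sd))
    ff <- pmin(0.6, pmax(0.02, stats::rnorm(n, config$fat_fraction_mean, config$fat_fraction_sd)))
    fat0 <- ff * bw0
    dbw <- stats::rnorm(n, config$class_delta_bw_pct[cls], config$within_class_sd_pct)
    dfat <- stats::rnorm(n, config$class_delta_fat_pct[cls], 2 * config$within_class_sd_pct)
    bw18 <- bw0 * (1 + dbw / 100)
    fat18 <- pmin(bw18 * 0.7, fat0 * (1 + dfat / 100))
    data.frame(
      animal_id = sprintf("m%02d", seq_len(n)),
      latent_class = factor(cls),
      bw_t0 = bw0, bw_t18 = bw18,
      fat_t0 = fat0, fat_t18 = fat18,
      lean_t0 = bw0 - fat0, lean_t18 = bw18 - fat18,
      stringsAsFactors = FALSE
    )
  })
}

#' Configuration for one synthetic expression study
#'
#' @param study_id study identifier.
#' @param platform `"microarray"` (log2 intensities) or `"rnaseq"`
#'   (negative-binomial counts).
#' @param n_per_class named integer vector of class sizes, e.g.
#'   `c(lean = 18, obese = 22)`. Two classes is the canonical case; more
#'   are allowed for the three-group single-study workflows, in which
#'   case the planted effect is graded linearly from 0 (first class) to 1
#'   (last class).
#' @param n_genes size of the gene universe before dropout.
#' @param batch_shift_sd SD (log2 units) of the additive per-study
#'   per-gene batch shift.
#' @param noise_sd residual SD (log2 units) of microarray intensities;
#'   planted microarray effects are expressed in units of this SD
#'   (standardized mean shifts).
#' @param nb_dispersion negative-binomial dispersion phi (variance =
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param libsize_mean,libsize_sd per-sample library size (reads).
#' @param gene_dropout_rate fraction of the gene universe absent from
#'   this study's panel.
#' @param species `"mouse"` (title-case gene symbols) or `"human"`
#'   (uppercase), exercising cross-species alignment.
#' @param seed integer seed.
#' @return a `StudyConfig` list.
#' @export
study_config <- function(study_id, platform = c("microarray", "rnaseq"),
                         n_per_class = c(lean = 18L, obese = 22L),
                         n_genes = 1000L,
                         batch_shift_sd = 0.5, noise_sd = 0.6,
                         nb_dispersion = 0.1,
                         libsize_mean = 2e6, libsize_sd = 2e5,
                         gene_dropout_rate = 0,
                         species = c("mouse", "human"),
                         seed = 1L) {
  platform <- match.arg(platform)
  species <- match.arg(species)
  if (length(n_per_class) < 2L) stopf("at least two classes are required")
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class)))) {
    stopf("n_per_class must be a named vector of class sizes")
  }
  if (any(n_per_class < 1)) stopf("every class needs at least one sample")
  check_number(gene_dropout_rate, "gene_dropout_rate", lower = 0, upper = 1 - 1e-12)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(batch_shift_sd, "batch_shift_sd", lower = 0)
  check_number(libsize_mean, "libsize_mean", lower = 1)
  check_number(libsize_sd, "libsize_sd", lower = 0)
  structure(list(
    study_id = as.character(study_id), platform = platform,
    n_per_class = as.integer(round(n_per_class)) |> stats::setNames(names(n_per_class)),
    n_genes = as.integer(n_genes),
    batch_shift_sd = batch_shift_sd, noise_sd = noise_sd,
    nb_dispersion = nb_dispersion,
    libsize_mean = libsize_mean, libsize_sd = libsize_sd,
    gene_dropout_rate = gene_dropout_rate,
    species = species, seed = as.integer(seed)
  ), class = "StudyConfig")
}

#' Planted discriminative signature (simulation ground truth)
#'
#' @param gene_ids canonical ids of the planted genes.
#' @param effect per-gene effect size, recycled to `length(gene_ids)`:
#'   standardized mean shift for microarray studies, log2 fold-change for
#'   RNA-seq studies. Signs are kept consistent across studies.
#' @return a `PlantedSignature` list.
#' @export
planted_signature <- function(gene_ids, effect = 1.5) {
  gene_ids <- canonical_gene_id(gene_ids)
  effect <- rep_len(effect, length(gene_ids))
  if (length(gene_ids) && any(!is.finite(effect))) stopf("effects must be finite")
  structure(list(gene_ids = gene_ids,
                 effect = stats::setNames(effect, gene_ids)),
            class = "PlantedSignature")
}

## Gene universe naming: canonical ids GENE0001..; mouse studies present
## them title-case, human studies uppercase.
gene_universe <- function(n_genes) sprintf("GENE%04d", seq_len(n_genes))

style_ids <- function(ids, species) {
  if (species == "mouse") {
    paste0(substr(ids, 1, 1), tolower(substr(ids, 2, nchar(ids))))
  } else ids
}

study_panel <- function(config) {
  ## per-study panel after seeded dropout; seed offset keeps the panel
  ## draw independent of the expression draws
  universe <- gene_universe(config$n_genes)
  n_drop <- floor(config$gene_dropout_rate * config$n_genes)
  if (n_drop == 0) return(universe)
  with_seed(config$seed + 104729L,
            sort(sample(universe, config$n_genes - n_drop)))
}

class_effect_multiplier <- function(k) {
  ## two classes: 0 for the first (lean/reference), 1 for the second;
  ## k > 2 classes: graded 0..1 so the planted genes separate all groups
  if (k == 1L) 1 else seq(0, 1, length.out = k)
}

#' Simulate a microarray study
#'
#' Log2 intensities are gene baseline + per-study per-gene batch shift +
#' planted class effect (signature genes only, scaled by `noise_sd` so
#' the standardized shift equals the configured effect) + Gaussian noise.
#'
#' @param config a [study_config()] with `platform = "microarray"`.
#' @param sig a [planted_signature()]; signature genes absent from this
#'   study's post-dropout panel are silently dropped from its truth (the
#'   carried set is recorded in `attr(, "carried_signature")`).
#' @return an [expression_study()].
#' @export
simulate_microarray_study <- function(config, sig = planted_signature(character(0))) {
  stopifnot(inherits(config, "StudyConfig"))
  if (config$platform != "microarray") stopf("config platform must be 'microarray'")
  panel <- study_panel(config)
  p <- length(panel)
  n <- sum(config$n_per_class)
  k <- length(config$n_per_class)
  cls <- rep(names(config$n_per_class), config$n_per_class)
  mult <- class_effect_multiplier(k)[match(cls, names(config$n_per_class))]
  carried <- intersect(sig$gene_ids, panel)
  effect <- numeric(p)
  effect[match(carried, panel)] <- sig$effect[carried] * config$noise_sd
  out <- with_seed(config$seed, {
    baseline <- stats::rnorm(p, mean = 8, sd = 2)
    batch <- stats::rnorm(p, 0, config$batch_shift_sd)
    m <- matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
    m <- m + baseline + batch + outer(effect, mult)
    m
  })
  study <- expression_study(out, class_labels = factor(cls, levels = names(config$n_per_class)),
                            study_id = config$study_id, platform = "microarray",
                            gene_ids = style_ids(panel, config$species),
                            sample_ids = sprintf("%s_s%02d", config$study_id, seq_len(n)),
                            species = config$species)
  attr(study, "carried_signature") <- carried
  study
}

#' Simulate an RNA-seq study
#'
#' Negative-binomial counts with per-sample library sizes; planted log2
#' fold-changes multiply the expected expression of signature genes in
#' the non-reference class(es).
#'
#' @inheritParams simulate_microarray_study
#' @param config a [study_config()] with `platform = "rnaseq"`.
#' @return an [expression_study()] of integer counts.
#' @export
simulate_rnaseq_study <- function(config, sig = planted_signature(character(0))) {
  stopifnot(inherits(config, "StudyConfig"))
  if (config$platform != "rnaseq") stopf("config platform must be 'rnaseq'")
  panel <- study_panel(config)
  p <- length(panel)
  n <- sum(config$n_per_class)
  k <- length(config$n_per_class)
  cls <- rep(names(config$n_per_class), config$n_per_class)
  mult <- class_effect_multiplier(k)[match(cls, names(config$n_per_class))]
  carried <- intersect(sig$gene_ids, panel)
  lfc <- numeric(p)
  lfc[match(carried, panel)] <- sig$effect[carried]
  out <- with_seed(config$seed, {
    ## relative abundances on log2 scale; batch shift also on log2 scale
    logab <- stats::rnorm(p, mean = 4, sd = 1.5) + stats::rnorm(p, 0, config$batch_shift_sd)
    ab <- 2^logab
    ab <- ab / sum(ab)
    libsize <- pmax(1e4, stats::rnorm(n, config$libsize_mean, config$libsize_sd))
    mu <- outer(ab, libsize) * 2^outer(lfc, mult)
    counts <- matrix(0L, p, n)
    pos <- mu > 0
    if (config$nb_dispersion == 0) {
      counts[pos] <- stats::rpois(sum(pos), mu[pos])
    } else {
      counts[pos] <- stats::rnbinom(sum(pos), size = 1 / config$nb_dispersion, mu = mu[pos])
    }
    counts
  })
  study <- expression_study(out, class_labels = factor(cls, levels = names(config$n_per_class)),
                            study_id = config$study_id, platform = "rnaseq",
                            gene_ids = style_ids(panel, config$species),
                            sample_ids = sprintf("%s_s%02d", config$study_id, seq_len(n)),
                            species = config$species)
  attr(study, "carried_signature") <- carried
  study
}

#' Simulate one study, dispatching on platform
#' @param config a [study_config()].
#' @param sig a [planted_signature()].
#' @return an [expression_study()].
#' @export
simulate_study <- function(config, sig = planted_signature(character(0))) {
  switch(config$platform,
         microarray = simulate_microarray_study(config, sig),
         rnaseq = simulate_rnaseq_study(config, sig))
}

#' Simulate a multi-study collection with a shared planted signature
#'
#' @param configs list of [study_config()] objects (>= 2 studies).
#' @param sig a [planted_signature()] shared (direction-consistent)
#'   across studies.
#' @param ortholog_map optional map passed to [study_collection()].
#' @return a [study_collection()] whose `truth` element records the
#'   planted gene set, per-study carried genes, and effects.
#' @export
simulate_multistudy_collection <- function(configs, sig = planted_signature(character(0)),
                                           ortholog_map = NULL) {
  if (length(configs) < 2L) stopf("at least two studies are required")
  studies <- lapply(configs, simulate_study, sig = sig)
  coll <- study_collection(studies, ortholog_map = ortholog_map)
  carried <- lapply(studies, attr, "carried_signature")
  names(carried) <- vapply(studies, `[[`, character(1), "study_id")
  coll$truth <- list(
    planted_genes = sig$gene_ids,
    effects = sig$effect,
    carried = carried,
    planted_in_shared = intersect(sig$gene_ids, coll$shared_genes)
  )
  coll
}

#' Default seven-study integration preset
#'
#' Emulates the structure of the integration stage: three mouse-like
#' studies (two microarray, one RNA-seq) and four human-like studies
#' (three microarray, one RNA-seq), each contrasting lean vs. obese with
#' mildly unbalanced classes, per-study batch shifts, and per-study
#' gene-panel dropout so the shared panel is a strict subset of the
#' universe.
#'
#' @param seed integer master seed; each study derives its own sub-seed.
#' @param n_genes gene universe size.
#' @param n_planted number of planted discriminative genes.
#' @param effect planted effect size (standardized shift / log2
#'   fold-change).
#' @param n_per_class class sizes used for every study.
#' @param gene_dropout_rate per-study dropout fraction.
#' @return list with `configs`, `signature`, and the assembled
#'   `collection`.
#' @export
integration_preset <- function(seed = 1L, n_genes = 600L, n_planted = 100L,
                               effect = 1.5,
                               n_per_class = c(lean = 18L, obese = 22L),
                               gene_dropout_rate = 0.05) {
  universe <- gene_universe(n_genes)
  sig <- with_seed(seed + 7L, {
    genes <- sample(universe, n_planted)
    planted_signature(genes, effect = effect * sample(c(-1, 1), n_planted, replace = TRUE))
  })
  plat <- c(mouse1 = "microarray", mouse2 = "microarray", mouse3 = "rnaseq",
            human1 = "microarray", human2 = "microarray", human3 = "rnaseq",
            human4 = "microarray")
  species <- c(rep("mouse", 3), rep("human", 4))
  configs <- lapply(seq_along(plat), function(i) {
    study_config(names(plat)[i], platform = plat[[i]], n_per_class = n_per_class,
                 n_genes = n_genes, gene_dropout_rate = gene_dropout_rate,
                 species = species[i], seed = seed + 100L * i)
  })
  list(configs = configs, signature = sig,
       collection = simulate_multistudy_collection(configs, sig))
}

#' Null seven-study preset (no planted genes)
#' @inheritParams integration_preset
#' @return as [integration_preset()], with an empty signature.
#' @export
null_preset <- function(seed = 1L, n_genes = 300L,
                        n_per_class = c(lean = 18L, obese = 22L)) {
  integration_preset(seed = seed, n_genes = n_genes, n_planted = 0L,
                     n_per_class = n_per_class)
}
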