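## Body-composition metrics, Ward.D2 stratification into sensitivity
## groups, and the cohort-level statistics (one-way ANOVA, Cohen's d,
## glucose-tolerance AUC).

#' Derive body-composition metrics
#'
#' Adiposity is fat mass expressed as a percentage of total body weight;
#' delta metrics are percent changes from T0 to T18 relative to the T0
#' value.
#'
#' @param p phenotype data frame with columns `bw_t0`, `bw_t18`,
#'   `fat_t0`, `fat_t18` (grams), as produced by [simulate_phenotypes()]
#'   or read from a TSV.
#' @return `p` with added columns `adiposity_t0`, `adiposity_t18` (%),
#'   `delta_bw_pct`, `delta_fat_pct`, `delta_adiposity_pct`.
#' @examples
#' derive_body_metrics(data.frame(bw_t0 = 40, bw_t18 = 60,
#'                                fat_t0 = 10, fat_t18 = 30))
#' @export
derive_body_metrics <- function(p) {
  req <- c("bw_t0", "bw_t18", "fat_t0", "fat_t18")
  miss <- setdiff(req, names(p))
  if (length(miss)) stopf("missing phenotype columns: %s", paste(miss, collapse = ", "))
  if (any(p$bw_t0 <= 0 | p$bw_t18 <= 0)) stopf("body weights must be positive")
  p$adiposity_t0 <- 100 * p$fat_t0 / p$bw_t0
  p$adiposity_t18 <- 100 * p$fat_t18 / p$bw_t18
  p$delta_bw_pct <- 100 * (p$bw_t18 - p$bw_t0) / p$bw_t0
  p$delta_fat_pct <- 100 * (p$fat_t18 - p$fat_t0) / p$fat_t0
  p$delta_adiposity_pct <- 100 * (p$adiposity_t18 - p$adiposity_t0) / p$adiposity_t0
  p
}

#' Stratify animals into sensitivity groups by Ward.D2 clustering
#'
#' Clusters animals on the six end-of-challenge body-composition
#' variables (`bw_t18`, `fat_t18`, `adiposity_t18`, `delta_bw_pct`,
#' `delta_fat_pct`, `delta_adiposity_pct`), z-scored, using Euclidean
#' distance and Ward.D2 linkage, then cuts the tree at `k` clusters.
#' Clusters are labelled by ascending mean percent body-weight gain:
#' `R` (resistant, lowest), `I` (intermediate), `P` (prone, highest) for
#' `k = 3`; `G1..Gk` otherwise. Ties in the mean are broken by mean
#' `delta_fat_pct`, then cluster index.
#'
#' @param metrics data frame containing the clustering variables (see
#'   [derive_body_metrics()]).
#' @param k number of groups (default 3).
#' @param variables clustering variable names.
#' @return a `GroupAssignment` list: `labels` (factor, one per animal,
#'   levels in ascending gain order), `cluster_means` (groups x
#'   variables), `merge_heights` (hclust heights), `hclust` (the tree).
#' @export
ward_cluster_groups <- function(metrics, k = 3L,
                                variables = c("bw_t18", "fat_t18", "adiposity_t18",
                                              "delta_bw_pct", "delta_fat_pct",
                                              "delta_adiposity_pct")) {
  miss <- setdiff(variables, names(metrics))
  if (length(miss)) stopf("missing clustering variables: %s", paste(miss, collapse = ", "))
  X <- as.matrix(metrics[, variables, drop = FALSE])
  n <- nrow(X)
  if (k > n) stopf("k = %d exceeds the number of animals (%d)", k, n)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("constant clustering variable(s): %s",
          paste(variables[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  ## order clusters by ascending mean delta_bw_pct (ties: delta_fat_pct,
  ## then cluster index)
  mean_by <- function(v) tapply(metrics[[v]], cl, mean)[as.character(seq_len(k))]
  ord <- order(mean_by("delta_bw_pct"), mean_by("delta_fat_pct"), seq_len(k))
  lab_names <- if (k == 3L) c("R", "I", "P") else paste0("G", seq_len(k))
  labels <- factor(lab_names[match(cl, ord)], levels = lab_names)
  cm <- do.call(rbind, lapply(ord, function(i) colMeans(X[cl == i, , drop = FALSE])))
  rownames(cm) <- lab_names
  structure(list(labels = labels, cluster_means = cm,
                 merge_heights = hc$height, hclust = hc, k = k),
            class = "GroupAssignment")
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F ratio and its F-distribution p-value,
#' computed with [stats::oneway.test()] under the equal-variance
#' assumption (the classical ANOVA F).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need a list of >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stopf("each group needs >= 2 values")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  grand <- mean(y)
  between_ss <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  if (within_ss == 0 && between_ss == 0) {
    stopf("degenerate ANOVA: zero within-group variance with equal means")
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(a) - mean(b)) / s` with `s` the pooled standard deviation
#' (denominator `n1 + n2 - 2`).
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return the effect size `d`.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 values")
  n1 <- length(a); n2 <- length(b)
  s <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  if (s == 0) stopf("pooled standard deviation is zero")
  (mean(a) - mean(b)) / s
}

#' Trapezoidal area under a time series
#'
#' Used to summarize oral-glucose-tolerance-test curves as area under the
#' glucose concentration over time (mg/dL x min).
#'
#' @param times strictly increasing time points (minutes).
#' @param values measurements at `times` (mg/dL).
#' @return the trapezoid-rule AUC.
#' @examples
#' trapezoid_auc(c(0, 15, 30, 60), c(5, 10, 8, 6))  # 457.5
#' @export
trapezoid_auc <- function(times, values) {
  if (length(times) < 2L) stopf("need >= 2 points")
  if (length(times) != length(values)) stopf("times and values differ in length")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
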