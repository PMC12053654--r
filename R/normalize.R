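## RNA-seq count preprocessing: CPM, low-expression filtering, TMM
## normalization factors and log2-CPM transformation.

check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts)) stopf("count matrix contains missing values")
  if (any(counts < 0)) stopf("counts must be non-negative")
  counts
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / (libsize_s * f_s) * 1e6` where the library
#' size is the column sum and `f_s` an optional TMM normalization factor.
#'
#' @param counts genes x samples non-negative count matrix.
#' @param factors per-sample normalization factors (default all 1), e.g.
#'   from [tmm_factors()].
#' @return matrix of counts per million, same dimnames as `counts`.
#' @export
cpm <- function(counts, factors = NULL) {
  counts <- check_counts(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- lib * factors
  if (any(eff <= 0)) stopf("zero or negative effective library size")
  sweep(counts, 2, eff, "/") * 1e6
}

#' Filter genes with low mean expression
#'
#' Genes whose mean CPM across all samples falls below the threshold are
#' rejected as low-expressed; genes at or above the threshold are kept
#' (order preserved).
#'
#' @param counts genes x samples count matrix.
#' @param min_mean_cpm keep genes with row-mean CPM `>=` this value
#'   (default 10).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_mean_cpm = 10) {
  counts <- check_counts(counts)
  keep <- rowMeans(cpm(counts)) >= min_mean_cpm
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization (computed with
#' \pkg{edgeR}): the reference library is the one whose upper-quartile
#' CPM is closest to the mean upper-quartile; per-sample factors are
#' precision-weighted means of M-values doubly trimmed on M (30%) and A
#' (5%), rescaled so their geometric mean is 1.
#'
#' @param counts genes x samples count matrix (>= 2 samples, each with a
#'   positive total).
#' @param trim_m,trim_a trim fractions for log-ratios and
#'   average-intensities.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- check_counts(counts)
  if (ncol(counts) < 2L) stopf("TMM needs >= 2 samples")
  if (any(colSums(counts) <= 0)) stopf("every sample needs at least one positive count")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  f <- f / geometric_mean(f)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (libsize * f + 2 * prior) * 1e6)`, a
#' variance-stabilized, linearized transform of the normalized counts.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample normalization factors (default 1).
#' @param prior prior count added to the numerator (default 0.5); the
#'   effective library size is offset by `2 * prior`.
#' @return matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  counts <- check_counts(counts)
  check_number(prior, "prior", lower = 1e-12)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- lib * factors
  if (any(eff <= 0)) stopf("zero or negative effective library size")
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}
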