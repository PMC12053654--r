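## Per-gene differential screening: vectorized one-way ANOVA F-tests on
## log-scale expression with Benjamini-Hochberg adjustment.

#' Per-gene one-way ANOVA F-test
#'
#' Computes the classical between/within mean-square F statistic and its
#' p-value for every gene (row) of a log-scale expression matrix, plus
#' Benjamini-Hochberg q-values. Genes with zero total variance are
#' flagged as constant and assigned `p = 1`.
#'
#' @param X genes x samples numeric matrix on the log scale.
#' @param groups per-sample group labels (>= 2 groups, each with >= 2
#'   samples).
#' @return a `DiffExpTable` data frame: `gene`, `F`, `p`, `q`, one mean
#'   column per group, and `constant` flag. Attribute `groups` records
#'   the group levels.
#' @export
per_gene_f_test <- function(X, groups) {
  X <- as.matrix(X)
  groups <- factor(groups)
  if (length(groups) != ncol(X)) stopf("groups length != number of samples")
  if (nlevels(groups) < 2L) stopf("need >= 2 groups")
  sizes <- tabulate(groups)
  if (any(sizes < 2L)) {
    stopf("group '%s' has fewer than 2 samples", levels(groups)[which(sizes < 2L)[1]])
  }
  n <- ncol(X); k <- nlevels(groups)
  ## vectorized group means and sums of squares
  G <- stats::model.matrix(~ 0 + groups)            # n x k indicator
  means <- X %*% G %*% diag(1 / sizes, k)           # genes x k
  grand <- rowMeans(X)
  ss_between <- as.numeric((means - grand)^2 %*% sizes)
  ss_total <- rowSums((X - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1; df2 <- n - k
  constant <- ss_total < 1e-12
  Fstat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  Fstat[constant] <- 0
  p[constant] <- 1
  out <- data.frame(gene = rownames(X) %||% as.character(seq_len(nrow(X))),
                    F = Fstat, p = p, q = bh_adjust(p),
                    constant = constant, stringsAsFactors = FALSE)
  colnames(means) <- paste0("mean_", levels(groups))
  out <- cbind(out, means)
  rownames(out) <- NULL
  attr(out, "groups") <- levels(groups)
  class(out) <- c("DiffExpTable", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values (via [stats::p.adjust()]),
#' returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' @param tab a `DiffExpTable` from [per_gene_f_test()].
#' @param alpha q-value threshold (default 0.05); the boundary is
#'   inclusive (`q <= alpha` is selected) unless `strict = TRUE`.
#' @param strict use a strict `q < alpha` rule.
#' @return character vector of selected gene ids.
#' @export
select_differential <- function(tab, alpha = 0.05, strict = FALSE) {
  if (!nrow(tab)) return(character(0))
  keep <- if (strict) tab$q < alpha else tab$q <= alpha
  tab$gene[keep]
}
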