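#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package funnel their seed through this
#' helper so that user-level RNG state is never disturbed and identical
#' seeds yield identical draws.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Canonicalize gene identifiers
#'
#' Gene symbols are compared case-insensitively across species: mouse
#' "Sfrp4" and human "SFRP4" map to the same canonical id. Canonical ids
#' are uppercase with surrounding whitespace stripped.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of canonical (uppercase) identifiers.
#' @examples
#' canonical_gene_id(c("Glul", "SFRP4", " Itih5 "))
#' @export
canonical_gene_id <- function(ids) {
  toupper(trimws(as.character(ids)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
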