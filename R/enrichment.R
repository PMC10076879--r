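#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of annotated genes drawn in a query of size
#' `n` from a universe of `N` genes of which `K` belong to the set —
#' identical to the one-sided Fisher exact test on the 2x2 table.
#'
#' @param k observed hits in the query (`0 <= k <= min(K, n)`).
#' @param K genes of the set present in the universe.
#' @param n query size.
#' @param N universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeomUpperTail(5, 5, 5, 10)   # 1 / choose(10, 5)
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited: set name, description, member genes. Delegates to
#' [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Over-representation analysis of a gene list
#'
#' Tests every gene set that intersects the universe with the
#' hypergeometric upper tail and adjusts across tested sets with BH. Query
#' genes outside the universe are dropped with a warning. The choice of
#' universe (platform genes for methylation lists, count-matrix genes for
#' expression lists) is the caller's and changes results materially.
#'
#' @param query character vector of genes of interest (non-empty).
#' @param universe character vector of all measurable genes.
#' @param collection named list of gene sets (see [readGMT()]).
#' @param dropEmpty drop sets with zero query hits instead of reporting
#'   them with p = 1 (default `FALSE`).
#' @return data.frame sorted by p-value: `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`.
#' @export
enrichGeneSets <- function(query, universe, collection, dropEmpty = FALSE) {
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0) stop("empty query gene list")
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query gene left inside the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p_value = hypergeomUpperTail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set intersects the universe")
  if (dropEmpty) res <- res[res$k > 0, , drop = FALSE]
  res$fdr <- bhAdjust(res$p_value)
  res <- res[order(res$p_value, -res$k, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
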