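#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability P(X >= k) of drawing at least k annotated genes
#' when sampling n genes without replacement from a universe of N genes of
#' which K carry the annotation.  Vectorized.
#'
#' @param N universe size.
#' @param K term (annotation) size.
#' @param n query size.
#' @param k overlap between query and term.
#' @return numeric vector of p-values.
#' @examples
#' hypergeom_test(20, 5, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeom_test <- function(N, K, n, k) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q_i = min over j >= rank(i) of m * p_(j) / j, capped at 1; invariant to
#' the input order.  Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each term of an annotation collection for over-representation of
#' the query genes with the one-sided hypergeometric test, adjusts across
#' all terms with Benjamini-Hochberg, keeps terms with raw p strictly below
#' `alpha` (or FDR below `fdr_max` when given), sorts by ascending FDR, then
#' descending overlap, then term id, and truncates to the top `top_k` rows.
#'
#' @param query_genes character vector of query gene ids.
#' @param collection named list of gene sets as from [read_gmt()].
#' @param alpha raw p-value cutoff (strict; default 0.01).
#' @param top_k number of rows to report (default 10; `Inf` for all).
#' @param universe background gene ids; default: the union of all collection
#'   members.  Query and terms are intersected with it.
#' @param fdr_max optional FDR cutoff applied instead of `alpha`.
#' @return data frame with columns `term_id`, `description`, `N`, `K`, `n`,
#'   `k`, `p`, `fdr`.
#' @export
enrich <- function(query_genes, collection, alpha = 0.01, top_k = 10,
                   universe = NULL, fdr_max = NULL) {
  empty <- data.frame(term_id = character(), description = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (length(collection) == 0L || length(query_genes) == 0L) return(empty)
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(collection, `[[`, "members"),
                              use.names = FALSE))
  }
  universe <- unique(universe)
  query <- intersect(unique(query_genes), universe)
  N <- length(universe)
  n <- length(query)
  K <- vapply(collection, function(t) length(intersect(t$members, universe)), 0L)
  k <- vapply(collection, function(t) length(intersect(t$members, query)), 0L)
  p <- hypergeom_test(N, K, n, k)
  fdr <- bh_fdr(p)
  out <- data.frame(
    term_id = names(collection),
    description = vapply(collection, `[[`, "", "description"),
    N = N, K = K, n = n, k = k, p = p, fdr = fdr,
    stringsAsFactors = FALSE, row.names = NULL
  )
  keep <- if (is.null(fdr_max)) out$p < alpha else out$fdr < fdr_max
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$fdr, -out$k, out$term_id), , drop = FALSE]
  if (is.finite(top_k) && nrow(out) > top_k) {
    out <- out[seq_len(top_k), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Multi-set overlap (Venn) counts
#'
#' Exact cardinalities of every intersection among two to four named gene
#' sets: for each non-empty subset S of set names, the size of the
#' intersection of the sets in S.
#'
#' @param named_sets named list of 2-4 character vectors.
#' @return list with `set_sizes` (named integer vector) and `intersections`
#'   (named integer vector; names join set names with "&").
#' @export
overlap_counts <- function(named_sets) {
  m <- length(named_sets)
  if (m < 2L || m > 4L) {
    stop("overlap_counts supports between 2 and 4 sets")
  }
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(named_sets, unique)
  sizes <- vapply(sets, length, 0L)
  combos <- unlist(lapply(2:m, function(r)
    utils::combn(names(sets), r, simplify = FALSE)), recursive = FALSE)
  inter <- vapply(combos, function(nm)
    length(Reduce(intersect, sets[nm])), 0L)
  names(inter) <- vapply(combos, paste, "", collapse = "&")
  list(set_sizes = sizes, intersections = inter)
}
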