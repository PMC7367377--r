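# Hypergeometric over-representation testing.
#
# For a universe of N genes, a known set of A genes, a query of n genes and
# an overlap of k genes, the enrichment p-value is the upper hypergeometric
# tail
#   p = 1 - sum_{i=0}^{k-1} C(A,i) C(N-A,n-i) / C(N,n) = P(X >= k),
# evaluated in log space so that very small p-values do not overflow the
# binomial coefficients; values that underflow double precision are reported
# as 0 with the log10 p-value retained.

#' Hypergeometric enrichment p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` for an overlap of `k`
#' genes between a query of size `n` and a known set of size `A` drawn from a
#' universe of `N` genes. Vectorized over `A`/`n`/`k`.
#'
#' @param N universe size.
#' @param A known-set size, `A <= N`.
#' @param n query-set size, `n <= N`.
#' @param k overlap size, `0 <= k <= min(A, n)`.
#' @return A data.frame with columns `N`, `A`, `n`, `k`, `p` and `log10_p`
#'   (exact even when `p` underflows to 0).
#' @export
hypergeometric_pvalue <- function(N, A, n, k) {
  df <- data.frame(N = N, A = A, n = n, k = k)
  with(df, {
    if (any(A > N | n > N | k > pmin(A, n) | k < 0 | N < 1)) {
      ssnet_error("invalid enrichment query: need 0 <= k <= min(A, n), A <= N, n <= N",
                  "ssnet_domain_error")
    }
  })
  df$p <- stats::phyper(df$k - 1, df$A, df$N - df$A, df$n, lower.tail = FALSE)
  df$log10_p <- stats::phyper(df$k - 1, df$A, df$N - df$A, df$n,
                              lower.tail = FALSE, log.p = TRUE) / log(10)
  df
}

#' Test a query gene set against every set of a collection
#'
#' Computes the overlap `k = |query ∩ set|` for each set and applies
#' [hypergeometric_pvalue()] with the collection's universe size. Query genes
#' outside the declared universe (when the universe membership is supplied)
#' raise a warning and are dropped from `n`.
#'
#' @param query_genes character vector of query gene ids.
#' @param collection a [gene_set_collection()] with `universe_size` set.
#' @param universe optional character vector of universe gene ids, used to
#'   drop out-of-universe query genes; by default only the size is known and
#'   the query is used as-is.
#' @param alpha significance flag threshold (default 0.05).
#' @return A data.frame, one row per set: `set`, `N`, `A`, `n`, `k`, `p`,
#'   `log10_p`, `significant`, `overlap` (comma-separated overlapping genes).
#' @export
enrich_collection <- function(query_genes, collection, universe = NULL,
                              alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  N <- collection$universe_size
  if (is.na(N)) ssnet_error("collection has no universe_size", "ssnet_domain_error")
  query_genes <- unique(as.character(query_genes))
  if (!is.null(universe)) {
    out_of <- setdiff(query_genes, universe)
    if (length(out_of)) {
      warning(sprintf("%d query gene(s) outside the universe dropped", length(out_of)))
      query_genes <- intersect(query_genes, universe)
    }
  }
  n <- length(query_genes)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    ov <- intersect(query_genes, set)
    hp <- hypergeometric_pvalue(N, length(set), n, length(ov))
    data.frame(set = nm, hp, significant = hp$p < alpha,
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Enrichment of degree-ranked functional-gene subsets
#'
#' For each degree threshold (strictly decreasing), takes the functional
#' genes with degree strictly greater than the threshold and tests them
#' against every set of the collection; results carry significance star bins
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05).
#'
#' @param functional_net a `functional_network`.
#' @param collection a [gene_set_collection()] with `universe_size` set.
#' @param degree_thresholds strictly decreasing numeric vector; use `-1` (or
#'   any negative value) for the full functional gene set.
#' @return A data.frame with one row per threshold x set: `degree_threshold`,
#'   `n_genes`, `set`, `N`, `A`, `n`, `k`, `p`, `log10_p`, `stars`, `empty`.
#' @export
ranked_subset_enrichment <- function(functional_net, collection,
                                     degree_thresholds = c(19, 9, 7, 5, 3, 1, -1)) {
  stopifnot(inherits(functional_net, "functional_network"))
  if (is.unsorted(rev(degree_thresholds), strictly = TRUE)) {
    ssnet_error("degree_thresholds must be strictly decreasing", "ssnet_config_error")
  }
  rows <- lapply(degree_thresholds, function(th) {
    genes <- names(functional_net$degree)[functional_net$degree > th]
    if (!length(genes)) {
      return(data.frame(degree_threshold = th, n_genes = 0L, set = NA_character_,
                        N = NA, A = NA, n = NA, k = NA, p = NA_real_,
                        log10_p = NA_real_, stars = NA_character_, empty = TRUE))
    }
    er <- enrich_collection(genes, collection)
    data.frame(degree_threshold = th, n_genes = length(genes),
               set = er$set, N = er$N, A = er$A, n = er$n, k = er$k,
               p = er$p, log10_p = er$log10_p, stars = p_stars(er$p),
               empty = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
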