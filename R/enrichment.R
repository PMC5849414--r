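#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a query of size `n`
#' drawn without replacement from a universe of `N` genes of which `K` carry
#' the annotation:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' The sum is accumulated in log space via [lchoose()] for numerical
#' stability. This is the one-sided overrepresentation test; depletion is not
#' assessed.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param n query size (n <= N).
#' @param K annotated-set size (K <= N).
#' @param N universe size.
#' @return upper-tail probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  for (v in list(k = k, n = n, K = K, N = N)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      stop_validation("hypergeometric arguments must be single non-negative ",
                      "integers")
    }
  }
  if (n > N) stop_validation("violated: n <= N (query larger than universe)")
  if (K > N) stop_validation("violated: K <= N (term larger than universe)")
  if (k > min(n, K)) stop_validation("violated: k <= min(n, K)")
  if (k == 0) return(1)
  i <- k:min(n, K)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the number of tests and caps at 1,
#' preserving order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Gene-set overrepresentation analysis
#'
#' Tests a query gene list against every term of a collection with the
#' hypergeometric upper-tail test and applies a Bonferroni correction across
#' all tested terms. Gene symbols are harmonized by case-folding and
#' de-duplicated before counting; query genes absent from the universe are
#' dropped (default) or raise an error, per `unknown_genes`.
#'
#' @param query character vector of gene symbols.
#' @param collection a gene-set collection as returned by [read_gmt()] or
#'   [simulate_geneset_universe()]: list with `terms` (named list of lists,
#'   each with `term_name` and `genes`) and `universe` (character vector).
#' @param unknown_genes `"drop"` (default) or `"error"`.
#' @return tibble with columns `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_raw`, `p_bonferroni`, sorted by `p_raw` then
#'   `term_id`.
#' @export
enrich <- function(query, collection, unknown_genes = c("drop", "error")) {
  unknown_genes <- match.arg(unknown_genes)
  universe <- unique(tolower(collection$universe))
  original <- query[!duplicated(tolower(query))]
  query <- unique(tolower(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    if (unknown_genes == "error") {
      stop_validation("query gene(s) absent from the universe: ",
                      paste(original[tolower(original) %in% outside],
                            collapse = ", "))
    }
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) {
    stop_validation("query is empty after harmonization against the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$terms), function(id) {
    term <- collection$terms[[id]]
    genes <- intersect(unique(tolower(term$genes)), universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    tibble::tibble(
      term_id = id,
      term_name = term$term_name %||% id,
      k = k, n = n, K = K, N = N,
      fold_enrichment = if (K > 0) (k / n) / (K / N) else 0,
      p_raw = hypergeom_upper_tail(k, n, K, N)
    )
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    stop_validation("collection contains no terms")
  }
  res$p_bonferroni <- bonferroni_adjust(res$p_raw)
  res[order(res$p_raw, res$term_id), , drop = FALSE]
}
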