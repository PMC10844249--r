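# Gene-set over-representation: one-tailed hypergeometric (Fisher exact)
# and the conservative EASE variant, with Bonferroni correction over the
# tested terms.  Stands in for DAVID in the substrate screen's stage 3.

#' Over-representation tail probability
#'
#' With a query of `n` features drawn from a background of `N`, of which `K`
#' belong to the term and `k` of the query overlap it:
#' \describe{
#'   \item{fisher}{upper hypergeometric tail `P(X >= k)` -- the one-tailed
#'     Fisher exact P.}
#'   \item{ease}{the EASE score: the same tail evaluated with the overlap
#'     reduced by one (`P(X >= k - 1)`), penalizing single-gene overlaps;
#'     `k` of 0 or 1 gives p = 1 by definition.}
#' }
#'
#' @param k query-term overlap count.
#' @param K term size within the background.
#' @param n query size.
#' @param N background size.
#' @param mode `"fisher"` or `"ease"`.
#' @return The tail probability, a single number in \[0, 1\].
#' @export
overrep_p <- function(k, K, n, N, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  for (v in c("k", "K", "n", "N")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val != round(val) || val < 0)
      validation_error(sprintf("'%s' must be a single non-negative integer", v))
  }
  if (k > min(K, n) || K > N || n > N)
    validation_error(sprintf(
      "inconsistent contingency counts: k=%d K=%d n=%d N=%d", k, K, n, N))
  kk <- if (mode == "ease") k - 1L else k
  if (kk <= 0L) return(1)
  # P(X >= kk) for X ~ Hypergeometric(N, K, n)
  phyper(kk - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests every term with at least one member inside the background;
#' Bonferroni correction spans exactly the tested terms.  Query ids must be
#' a subset of the background (a mismatched universe is a configuration
#' mistake, not data).
#'
#' @param query character vector of feature ids (the candidate list).
#' @param background character vector of feature ids (the universe).
#' @param sets a [gene_set_collection()].
#' @param mode `"ease"` (default, DAVID-like) or `"fisher"`.
#' @param alpha significance threshold applied to the Bonferroni-adjusted P
#'   (default 0.05).
#' @return data.frame sorted by `p_raw` then `term_id` with columns
#'   `term_id`, `description`, `k`, `K`, `n`, `N`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
enrich <- function(query, background, sets, mode = c("ease", "fisher"),
                   alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!all(query %in% background))
    validation_error("query contains features absent from the background")
  if (length(query) == 0L) {
    os_log("enrich: empty query, returning no results")
    return(data.frame(term_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  N <- length(background); n <- length(query)
  Ks <- vapply(sets$sets, function(m) sum(m %in% background), 0L)
  tested <- names(sets$sets)[Ks >= 1L]
  ks <- vapply(sets$sets[tested], function(m) sum(query %in% m), 0L)
  p_raw <- mapply(function(k, K) overrep_p(k, K, n, N, mode = mode),
                  ks, Ks[tested])
  m_tests <- length(tested)
  res <- data.frame(term_id = tested,
                    description = unname(sets$descriptions[tested]),
                    k = unname(ks), K = unname(Ks[tested]),
                    n = n, N = N, p_raw = unname(p_raw),
                    p_bonferroni = pmin(1, unname(p_raw) * m_tests),
                    stringsAsFactors = FALSE)
  res$significant <- res$p_bonferroni < alpha
  res <- res[order(res$p_raw, res$term_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
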