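#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (order-preserving,
#' clipped at 1, with running-minimum monotonicity). Input is validated and
#' the adjustment delegated to [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# log-space upper-tail hypergeometric: P(X >= k) for X ~ Hyper(N, M, n)
.hyper_upper <- function(k, N, M, n) {
  if (k <= 0) return(1)
  i <- k:min(n, M)
  if (!length(i) || k > min(n, M)) return(0)
  terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(terms)
  min(exp(mx + log(sum(exp(terms - mx)))), 1)
}

#' Hypergeometric over-representation test for gene sets
#'
#' For each term, with `N` background genes of which `M` carry the term,
#' and a query of `n` genes of which `k` carry it, the enrichment p-value
#' is the exact upper tail
#' `p = 1 - sum_{i=0}^{k-1} C(N-M, n-i) C(M, i) / C(N, n)`,
#' evaluated as the complementary sum in log space for numerical stability.
#' P-values are Benjamini-Hochberg adjusted across terms.
#'
#' @param query character vector of query genes (subset of `background`).
#' @param term_sets named list: term id -> character vector of genes
#'   (intersected with the background before counting).
#' @param background character vector of background genes.
#' @return data.frame of class `enrichment_result` with columns `term`,
#'   `N`, `M`, `n`, `k`, `p`, `q`, sorted by p.
#' @export
hypergeom_enrichment <- function(query, term_sets, background) {
  query <- unique(query); background <- unique(background)
  if (!length(query)) stop("empty query")
  if (!length(background)) stop("empty background")
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (!length(term_sets)) stop("no term sets supplied")
  if (is.null(names(term_sets))) stop("term_sets must be named")
  N <- length(background); n <- length(query)
  rows <- lapply(names(term_sets), function(tm) {
    genes <- intersect(unique(term_sets[[tm]]), background)
    M <- length(genes)
    k <- length(intersect(query, genes))
    data.frame(term = tm, N = N, M = M, n = n, k = k,
               p = .hyper_upper(k, N, M, n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
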