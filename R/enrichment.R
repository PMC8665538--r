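# Over-representation analysis (ORA) of a query gene list against annotation
# term sets, database-agnostic: terms arrive as GMT, the universe is supplied
# by the caller (the natural default being the background PPI gene space the
# candidates were drawn from).

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes
#' from a universe of `N` containing `K` term genes. Equal to the one-sided
#' Fisher exact p-value of the corresponding 2x2 table.
#'
#' @param k overlap count between query and term.
#' @param n query size within the universe.
#' @param K term size within the universe.
#' @param N universe size.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_upper_tail(2, 2, 2, 4) # 1/6
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 0, n <= N, K <= N,
            k <= min(n, K))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against annotation terms
#'
#' Query genes outside the universe are dropped (logged); each term is
#' clipped to the universe and retained only if its in-universe size lies in
#' `[min_term, max_term]`. BH adjustment is applied across the retained
#' terms.
#'
#' @param query character vector of gene ids (e.g. candidate drivers).
#' @param terms list of [gene_set()] annotation terms.
#' @param universe character vector of gene ids defining the sampling space.
#' @param min_term,max_term in-universe term-size window (defaults 5, 2000).
#' @return data.frame `(term, k, n, K, N, p, p_adj)` sorted by p then term
#'   name.
#' @export
enrich <- function(query, terms, universe, min_term = 5L, max_term = 2000L) {
  universe <- unique(as.character(universe))
  query0 <- unique(as.character(query))
  query <- intersect(query0, universe)
  if (length(query) < length(query0)) {
    an_log("dropped ", length(query0) - length(query),
           " query gene(s) outside the universe")
  }
  if (length(query) == 0L) stop_an("query is empty after universe intersection")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(terms, function(tm) {
    tg <- intersect(tm$genes, universe)
    K <- length(tg)
    if (K < min_term || K > max_term) return(NULL)
    k <- length(intersect(query, tg))
    data.frame(term = tm$name, k = k, n = n, K = K, N = N,
               p = hypergeom_upper_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  rows$p_adj <- bh_adjust(rows$p)
  rows <- rows[order(rows$p, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
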