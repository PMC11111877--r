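#' Contingency counts for a hypergeometric enrichment test
#'
#' In the over-representation setting: \code{N} genes in the background
#' universe, \code{M} of them carrying the attribute (term members), \code{n}
#' genes drawn (the query set), \code{k} hits (query members carrying the
#' attribute).
#'
#' @param N population size.
#' @param M attribute-positive population count.
#' @param n draws.
#' @param k hits.
#' @return an object of class `contingency_counts`.
#' @export
contingency_counts <- function(N, M, n, k) {
  vals <- c(N = N, M = M, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (M > N || n > N) stop("M and n must not exceed N", call. = FALSE)
  if (k > min(M, n) || k < max(0, n - (N - M))) {
    stop("k outside the hypergeometric support", call. = FALSE)
  }
  structure(as.list(vals), class = "contingency_counts")
}

#' Hypergeometric point mass P(X = k)
#'
#' The probability of exactly \code{k} hits when drawing \code{n} genes from a
#' universe of \code{N} containing \code{M} attribute-positive genes:
#' C(M,k) C(N-M,n-k) / C(N,n). Evaluated in log space.
#'
#' @param counts a `contingency_counts` object.
#' @return probability in [0, 1].
#' @export
hypergeom_pmf <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  stats::dhyper(counts$k, counts$M, counts$N - counts$M, counts$n)
}

#' Hypergeometric upper tail P(X >= k)
#'
#' The over-representation p-value: the sum of \code{hypergeom_pmf} over
#' k' = k ... min(M, n).
#'
#' @inheritParams hypergeom_pmf
#' @return probability in [0, 1].
#' @export
hypergeom_upper_tail <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  stats::phyper(counts$k - 1, counts$M, counts$N - counts$M, counts$n,
                lower.tail = FALSE)
}

#' Hypergeometric term enrichment of a query gene set
#'
#' Tests each term for over-representation of the query genes against the
#' supplied universe, adjusts across all tested terms with Benjamini-Hochberg,
#' and filters to p < alpha_p and q < alpha_q. Terms with no hits get p = 1
#' and are kept before filtering so BH denominators cover all terms tested.
#'
#' @param query character vector of query genes (an omics gene set), or an
#'   `omics_gene_set` object.
#' @param terms named list of character vectors (the term database).
#' @param universe character vector of background genes. Query genes outside
#'   the universe are dropped with a warning.
#' @param alpha_p,alpha_q retention thresholds on p and q (defaults 0.05).
#' @param source_name label recorded in the `source` column.
#' @return data.frame with columns term, source, N, M, n, k, p, q, hit_genes
#'   (semicolon-joined), sorted by p then term id.
#' @export
enrich_terms <- function(query, terms, universe,
                         alpha_p = 0.05, alpha_q = 0.05,
                         source_name = "query") {
  if (inherits(query, "omics_gene_set")) {
    source_name <- query$source
    query <- query$genes
  }
  .check_ids(universe, "universe genes")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  empty <- data.frame(term = character(), source = character(),
                      N = integer(), M = integer(), n = integer(),
                      k = integer(), p = numeric(), q = numeric(),
                      hit_genes = character(), stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("query empty after intersecting with the universe")
    return(empty)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tid) {
    tg <- intersect(terms[[tid]], universe)
    hits <- intersect(query, tg)
    k <- length(hits)
    p <- if (k == 0) 1 else {
      hypergeom_upper_tail(contingency_counts(N, length(tg), n, k))
    }
    data.frame(term = tid, source = source_name, N = N, M = length(tg),
               n = n, k = k, p = p,
               hit_genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[tab$p < alpha_p & tab$q < alpha_q, , drop = FALSE]
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("term", "source", "N", "M", "n", "k", "p", "q", "hit_genes")]
}
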