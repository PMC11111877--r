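#' Cohen's kappa between two terms' gene memberships
#'
#' Treats each term as a binary classification of the universe (member /
#' non-member) and returns the chance-corrected agreement between the two
#' classifications: kappa = (po - pe) / (1 - pe), where po is the observed
#' agreement (a + d) / N and pe the agreement expected from the marginal
#' membership rates. This is the DAVID-style term-term agreement used to
#' cluster enrichment results.
#'
#' @param term_a,term_b character vectors of member genes; must be subsets of
#'   the universe.
#' @param universe background gene ids.
#' @return kappa in [-1, 1]. If pe = 1 (both sets empty or both equal to the
#'   whole universe) the limit is taken: 1 for identical sets, 0 otherwise.
#' @export
kappa_pair <- function(term_a, term_b, universe) {
  .check_ids(universe, "universe genes")
  term_a <- unique(term_a); term_b <- unique(term_b)
  if (length(setdiff(term_a, universe)) || length(setdiff(term_b, universe))) {
    stop("term gene sets must be subsets of the universe", call. = FALSE)
  }
  N <- length(universe)
  a <- length(intersect(term_a, term_b))
  b <- length(term_a) - a
  c <- length(term_b) - a
  d <- N - a - b - c
  po <- (a + d) / N
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    return(if (a == length(term_a) && a == length(term_b)) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Kappa agreement and distance matrix over enriched terms
#'
#' Pools the enriched terms from all sources' enrichment tables (a term
#' enriched in several sources appears once; its source multiplicity is kept
#' in the `term_sources` component), computes the pairwise Cohen's kappa
#' matrix over the universe, and derives the dissimilarity d = 1 - kappa
#' used for neighbor joining.
#'
#' @param tables a single enrichment table or a list of tables from
#'   \code{\link{enrich_terms}}.
#' @param terms the term database (named list of gene vectors).
#' @param universe background gene ids.
#' @return an object of class `kappa_distance` with components `labels`,
#'   `kappa` (unit diagonal), `distance` (zero diagonal, in [0, 2]), and
#'   `term_sources` (data.frame term/source).
#' @export
build_kappa_distance_matrix <- function(tables, terms, universe) {
  if (is.data.frame(tables)) tables <- list(tables)
  pooled <- do.call(rbind, lapply(tables, function(t) t[, c("term", "source")]))
  labels <- sort(unique(pooled$term))
  if (length(labels) < 3) {
    stop("need at least 3 distinct enriched terms for neighbor joining",
         call. = FALSE)
  }
  missing <- setdiff(labels, names(terms))
  if (length(missing)) {
    stop("enriched term(s) absent from the term database: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(terms[labels], intersect, y = universe)
  m <- length(labels)
  kap <- diag(1, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      kap[i, j] <- kap[j, i] <- kappa_pair(sets[[i]], sets[[j]], universe)
    }
  }
  dimnames(kap) <- list(labels, labels)
  dist_mat <- 1 - kap
  diag(dist_mat) <- 0
  structure(list(labels = labels, kappa = kap, distance = dist_mat,
                 term_sources = pooled[order(pooled$term, pooled$source), ]),
            class = "kappa_distance")
}
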