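#' Neighbor-joining tree from a distance matrix
#'
#' Bottom-up Saitou-Nei agglomeration: at each step the pair (i, j)
#' minimizing Q(i, j) = (r - 2) d(i, j) - R_i - R_j is joined (R_i = row sum,
#' r = active node count), branch lengths follow the standard formulas, and
#' the reduced matrix uses d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2.
#' Negative branch-length estimates are clamped to zero with the deficit
#' moved to the sibling branch. On additive inputs the generating tree is
#' recovered exactly. Ties in Q are broken by column-major matrix order, so
#' the output is deterministic.
#'
#' @param dm a `kappa_distance` object or a symmetric numeric matrix with
#'   zero diagonal and row/column names.
#' @return an unrooted `phylo` tree (ape) whose tips are the matrix labels.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "kappa_distance")) dm$distance else as.matrix(dm)
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 labels")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")

  labels <- rownames(d)
  # each active node is represented by its Newick subtree string
  node <- labels
  while (length(node) > 3) {
    r <- length(node)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    idx <- which.min(q)                       # column-major, deterministic
    i <- (idx - 1) %% r + 1
    j <- (idx - 1) %/% r + 1
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_node <- sprintf("(%s:%.15g,%s:%.15g)", node[i], bi, node[j], bj)
    keep <- setdiff(seq_len(r), c(i, j))
    du <- pmax((d[i, keep] + d[j, keep] - d[i, j]) / 2, 0)
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du), c(du, 0))
    node <- c(node[keep], new_node)
  }
  # final three-way join: closed-form branch lengths
  b1 <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  b2 <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  b3 <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  newick <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                    node[1], b1, node[2], b2, node[3], b3)
  ape::read.tree(text = newick)
}

#' Cut a neighbor-joining tree into K modules
#'
#' Removes the K - 1 longest internal branches (branches between two internal
#' nodes); the connected components of the remaining tree define the modules.
#' If the tree has fewer internal branches than K - 1 (e.g. a star tree),
#' the longest terminal branches are removed next, so K up to the leaf count
#' is always attainable. Ties are broken by edge index for determinism.
#' Modules are numbered by size descending, then by lexicographically
#' smallest member term.
#'
#' @param tree a `phylo` tree from \code{\link{nj_tree}}.
#' @param K number of modules, 1 <= K <= leaf count.
#' @return named integer vector: term -> module id in 1..K' (K' <= K when a
#'   removed terminal branch isolates no extra leaf component).
#' @export
cut_tree <- function(tree, K) {
  stopifnot(inherits(tree, "phylo"))
  n_leaf <- length(tree$tip.label)
  if (K < 1 || K > n_leaf) stop("K must be between 1 and the leaf count")
  edges <- tree$edge
  lens <- tree$edge.length
  is_internal <- edges[, 2] > n_leaf
  ord <- order(!is_internal, -lens, seq_along(lens))   # internal first
  drop <- if (K > 1) ord[seq_len(K - 1)] else integer(0)
  keep <- setdiff(seq_len(nrow(edges)), drop)

  # connected components over the kept edges
  n_nodes <- max(edges)
  comp <- seq_len(n_nodes)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (e in keep) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) comp[min(a, b)] <- max(a, b)
  }
  leaf_comp <- vapply(seq_len(n_leaf), find, 0L)
  groups <- split(tree$tip.label, leaf_comp)
  first_member <- vapply(groups, function(g) min(g), "")
  groups <- groups[order(-lengths(groups), first_member)]
  assignment <- integer(n_leaf)
  names(assignment) <- tree$tip.label
  for (m in seq_along(groups)) assignment[groups[[m]]] <- m
  assignment[tree$tip.label]
}

#' Summarize module composition by omics source
#'
#' For each module: the member terms, the number of member terms contributed
#' by each source (from the enrichment term-source pairs), the union of
#' member-term genes with each gene's best absolute logFC across sources,
#' and per-source ranked gene lists (member-term genes intersected with the
#' source set, ordered by logFC descending, ties by gene id) ready for
#' preranked GSEA.
#'
#' @param partition named integer vector from \code{\link{cut_tree}}.
#' @param sources list of `omics_gene_set` objects (see
#'   \code{\link{omics_gene_set}}).
#' @param terms the term database (named list of gene vectors).
#' @param term_sources data.frame with columns term and source (e.g. the
#'   `term_sources` component of \code{\link{build_kappa_distance_matrix}});
#'   optional — source counts are omitted when absent.
#' @return list of per-module summaries (class `module_summary`).
#' @export
summarize_modules <- function(partition, sources, terms, term_sources = NULL) {
  stopifnot(all(names(partition) %in% names(terms)))
  src_names <- vapply(sources, function(s) s$source, "")
  names(sources) <- src_names
  out <- lapply(sort(unique(partition)), function(m) {
    member_terms <- names(partition)[partition == m]
    union_genes <- sort(unique(unlist(terms[member_terms], use.names = FALSE)))
    # best |logFC| per gene over all sources carrying it
    best <- rep(NA_real_, length(union_genes))
    names(best) <- union_genes
    per_source <- lapply(sources, function(s) {
      hit <- intersect(union_genes, s$genes)
      lfc <- s$logfc[hit]
      hit <- hit[order(-lfc, hit)]
      data.frame(gene = hit, logfc = s$logfc[hit], row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    for (s in sources) {
      hit <- intersect(union_genes, s$genes)
      best[hit] <- pmax(best[hit], abs(s$logfc[hit]), na.rm = TRUE)
    }
    counts <- if (!is.null(term_sources)) {
      ts <- unique(term_sources[term_sources$term %in% member_terms, ])
      vapply(src_names, function(s) sum(ts$source == s), 0L)
    } else NULL
    list(module = m, terms = member_terms, n_terms = length(member_terms),
         source_counts = counts, union_genes = union_genes,
         best_abs_logfc = best, ranked_by_source = per_source)
  })
  class(out) <- "module_summary"
  out
}
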