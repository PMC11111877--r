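#' Scoring configuration for ssGSEA / GSEA
#'
#' @param alpha rank-weight exponent for ssGSEA (default 0.25, the
#'   single-sample convention).
#' @param gsea_weight exponent on |score| for the GSEA running sum
#'   (default 1, the weighted statistic).
#' @param n_perm permutation count for the GSEA null.
#' @param seed integer seed for the permutation null.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(alpha = 0.25, gsea_weight = 1, n_perm = 1000L,
                           seed = 1L) {
  stopifnot(alpha >= 0, n_perm >= 1)
  structure(list(alpha = alpha, gsea_weight = gsea_weight,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "scoring_config")
}

#' Build a ranked signature from per-gene scores
#'
#' Sorts descending by score, ties broken by gene id ascending; genes must
#' be unique.
#'
#' @param scores named numeric vector of per-gene scores.
#' @return named numeric vector sorted as a `ranked_signature`.
#' @export
ranked_signature <- function(scores) {
  .check_ids(names(scores), "signature genes")
  scores[order(-scores, names(scores))]
}

# internal: GSEA running-sum extremum for hits at sorted positions `pos`
# (1-based in the ranked signature), with weights `w` at those positions and
# signature length N. Returns es and the extremum's hit index (for the
# leading edge).
.gsea_es <- function(pos, w, N) {
  k <- length(pos)
  W <- sum(w)
  if (W == 0) { w <- rep(1, k); W <- k }
  miss <- 1 / (N - k)
  cw <- cumsum(w) / W
  at_hit <- cw - (pos - seq_len(k)) * miss          # value just after hit j
  before_hit <- c(0, cw[-k]) - (pos - seq_len(k)) * miss  # just before hit j
  hi <- max(at_hit); lo <- min(c(before_hit, 0))
  if (hi >= abs(lo)) {
    list(es = hi, hit_index = which.max(at_hit), positive = TRUE)
  } else {
    list(es = lo, hit_index = which.min(before_hit), positive = FALSE)
  }
}

#' Single-sample GSEA (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (descending, ties by gene
#' id); the score is the integrated difference between the rank-weighted
#' ECDF of the gene set and the uniform ECDF of the remaining genes, with
#' rank weight |rank|^alpha (rank N for the top gene). Being purely
#' rank-based, the score is invariant under any monotone per-sample
#' transform of expression. Scores are min-max normalized across samples to
#' [0, 1].
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param gene_set character vector; members absent from `expr` rows are
#'   dropped with a warning.
#' @param config a \code{\link{scoring_config}}.
#' @return named numeric vector of per-sample scores in [0, 1].
#' @export
ssgsea_score <- function(expr, gene_set, config = scoring_config()) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  gene_set <- unique(gene_set)
  absent <- setdiff(gene_set, rownames(expr))
  if (length(absent) == length(gene_set)) {
    stop("no gene_set member present in the expression matrix")
  }
  if (length(absent)) {
    warning(sprintf("%d gene(s) absent from expression dropped",
                    length(absent)))
    gene_set <- setdiff(gene_set, absent)
  }
  N <- nrow(expr)
  k <- length(gene_set)
  if (k == N) stop("gene_set must not cover the whole expression matrix")
  hit <- rownames(expr) %in% gene_set
  raw <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], rownames(expr))
    h <- hit[ord]
    w <- ((N:1)^config$alpha) * h
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(!h) / (N - k)
    sum(p_hit - p_miss)
  }, 0)
  rng <- range(raw)
  out <- if (rng[1] == rng[2]) rep(0, length(raw)) else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  names(out) <- colnames(expr)
  out
}

#' Per-gene correlation with a sample-level trait
#'
#' Pearson correlation of each gene's expression against a per-sample trait
#' (e.g. a plasticity score); the positive-correlation genes are retained,
#' as in the gene-significance step of WGCNA-style trait analysis. Genes
#' with zero variance have undefined correlation and are recorded as NA in
#' the full table and excluded from the retained list.
#'
#' @param expr genes x samples matrix.
#' @param trait numeric vector, one value per sample (aligned order).
#' @return list with `full` (data.frame gene, r) and `retained` (r > 0,
#'   sorted descending).
#' @export
gene_trait_correlation <- function(expr, trait) {
  stopifnot(is.matrix(expr), length(trait) == ncol(expr))
  sds <- apply(expr, 1, stats::sd)
  r <- rep(NA_real_, nrow(expr))
  ok <- sds > 0 & stats::sd(trait) > 0
  if (any(ok)) r[ok] <- drop(stats::cor(t(expr[ok, , drop = FALSE]), trait))
  full <- data.frame(gene = rownames(expr), r = r, stringsAsFactors = FALSE)
  retained <- full[!is.na(full$r) & full$r > 0, , drop = FALSE]
  retained <- retained[order(-retained$r, retained$gene), , drop = FALSE]
  rownames(retained) <- NULL
  list(full = full, retained = retained)
}

#' Preranked GSEA with permutation null and leading edge
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum: hits increment by
#' |score|^gsea_weight (normalized over set hits), misses decrement by
#' 1/(N - N_hit); ES is the extremum. The null resamples size-matched random
#' gene sets (gene-label permutation) n_perm times under the config seed;
#' p = (1 + #[|null ES| >= |observed ES|]) / (1 + n_perm) — the magnitude
#' comparison makes p uniform on (0, 1] under the null with minimal value
#' 1/(1 + n_perm) — and NES = ES / mean(|null ES| of the same sign). The
#' leading edge contains
#' the hit genes at or before the extremum for positive ES (at or after it
#' for negative ES).
#'
#' @param signature a \code{\link{ranked_signature}}.
#' @param gene_set character vector; must intersect the signature and not
#'   cover it entirely.
#' @param config a \code{\link{scoring_config}}.
#' @return list of class `es_result`: es, nes, p, leading_edge, n_hits.
#' @export
preranked_gsea <- function(signature, gene_set, config = scoring_config()) {
  genes <- names(signature)
  N <- length(genes)
  gene_set <- unique(gene_set)
  pos <- which(genes %in% gene_set)
  if (!length(pos)) stop("gene_set does not intersect the signature")
  if (length(pos) == N) stop("gene_set must not cover the whole signature")
  k <- length(pos)
  wts <- abs(signature)^config$gsea_weight
  obs <- .gsea_es(pos, wts[pos], N)
  null_es <- .with_seed(config$seed, {
    vapply(seq_len(config$n_perm), function(b) {
      p <- sort(sample.int(N, k))
      .gsea_es(p, wts[p], N)$es
    }, 0)
  })
  same_sign <- if (obs$positive) null_es[null_es >= 0] else null_es[null_es <= 0]
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + config$n_perm)
  denom <- if (length(same_sign)) mean(abs(same_sign)) else mean(abs(null_es))
  nes <- if (denom > 0) obs$es / denom else 0
  le <- if (obs$positive) {
    genes[pos[seq_len(obs$hit_index)]]
  } else {
    genes[pos[obs$hit_index:k]]
  }
  structure(list(es = obs$es, nes = nes, p = p, leading_edge = le,
                 n_hits = k), class = "es_result")
}

#' Lineage-plasticity scoring pipeline
#'
#' End-to-end: (1) per-sample plasticity score by ssGSEA on the union of the
#' plasticity gene sets; (2) correlation of the module genes with that score
#' (positives retained); (3) a differential ranking between the high- and
#' low-score sample halves (median split, difference of group means); (4)
#' preranked GSEA of each pathway set against that ranking, with leading
#' edges. Deterministic under the config seed.
#'
#' @param expr genes x samples matrix.
#' @param plasticity_sets list of gene vectors defining the plasticity
#'   phenotype.
#' @param module_genes genes of the function module to correlate.
#' @param pathway_sets named list of pathway gene vectors to test.
#' @param config a \code{\link{scoring_config}}.
#' @return list: scores, correlation (see
#'   \code{\link{gene_trait_correlation}}), high_samples, ranking, gsea
#'   (named list of `es_result`).
#' @export
plasticity_pipeline <- function(expr, plasticity_sets, module_genes,
                                pathway_sets, config = scoring_config()) {
  if (ncol(expr) < 4) stop("need at least 4 samples for a median split")
  scores <- ssgsea_score(expr, unique(unlist(plasticity_sets)), config)
  module_genes <- intersect(module_genes, rownames(expr))
  if (!length(module_genes)) stop("module_genes do not intersect expression")
  corr <- gene_trait_correlation(expr[module_genes, , drop = FALSE], scores)
  high <- scores > stats::median(scores)
  if (!any(high) || all(high)) {       # all-tied scores: split by order
    high <- seq_along(scores) <= length(scores) / 2
  }
  ranking <- ranked_signature(
    rowMeans(expr[, high, drop = FALSE]) -
      rowMeans(expr[, !high, drop = FALSE]))
  gsea <- lapply(pathway_sets, preranked_gsea, signature = ranking,
                 config = config)
  list(scores = scores, correlation = corr,
       high_samples = colnames(expr)[high], ranking = ranking, gsea = gsea)
}
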