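#' A transcription-factor regulon with signed target modes
#'
#' @param tf TF identifier.
#' @param targets unique target gene ids.
#' @param modes regulation modes aligned to targets: +1/-1 (or reals in
#'   [-1, 1]).
#' @return a `regulon` object.
#' @export
regulon <- function(tf, targets, modes) {
  .check_ids(targets, "regulon targets")
  stopifnot(length(modes) == length(targets), all(abs(modes) <= 1))
  names(modes) <- targets
  structure(list(tf = tf, targets = targets, modes = modes),
            class = "regulon")
}

#' TF knockdown-signature enrichment against a target set
#'
#' For each TF, counts the overlap k between the genes affected by its
#' knockdown and the target set (e.g. the leading-edge genes), computes the
#' hypergeometric upper-tail p over the universe, BH-adjusts across TFs,
#' and flags TFs whose overlap exceeds min_hits (default 14, i.e. "> 14"
#' leading-edge genes).
#'
#' @param signatures named list: TF -> character vector of affected genes.
#' @param target_set gene vector, subset of the universe.
#' @param universe background gene ids.
#' @param min_hits retention threshold; the filtered view keeps k >
#'   min_hits.
#' @return data.frame tf, k, p, q, pass (k > min_hits), sorted by k
#'   descending then p.
#' @export
tf_knockdown_enrichment <- function(signatures, target_set, universe,
                                    min_hits = 14L) {
  .check_ids(universe, "universe genes")
  if (length(setdiff(target_set, universe))) {
    stop("target_set must be a subset of the universe")
  }
  if (!length(signatures)) {
    return(data.frame(tf = character(), k = integer(), p = numeric(),
                      q = numeric(), pass = logical(),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(unique(target_set))
  rows <- lapply(names(signatures), function(tf) {
    affected <- intersect(unique(signatures[[tf]]), universe)
    k <- length(intersect(affected, target_set))
    p <- if (k == 0) 1 else {
      hypergeom_upper_tail(contingency_counts(N, length(affected), n, k))
    }
    data.frame(tf = tf, k = k, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, "BH")
  tab$pass <- tab$k > min_hits
  tab <- tab[order(-tab$k, tab$p, tab$tf), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Regulon-based TF activity from a ranked signature
#'
#' A rank-based, mode-signed activity statistic in the spirit of
#' VIPER/aREA: signature scores are rank-transformed to (0, 1); each TF's
#' statistic is the mean over its targets of mode x (2 rank_fraction - 1).
#' Positive values mean the TF's positively regulated targets sit high in
#' the signature (activation), negative values repression. The null
#' resamples size-matched random target sets with random +/-1 modes; the
#' z-score and two-sided p follow, with BH adjustment across TFs. Regulons
#' with fewer than 3 targets present in the signature are skipped with a
#' warning.
#'
#' @param signature a \code{\link{ranked_signature}}.
#' @param regulons list of \code{\link{regulon}} objects.
#' @param n_perm null resample count.
#' @param seed integer seed for the null.
#' @return data.frame tf, n_targets, activity, z, p, q, sorted by z
#'   descending.
#' @export
regulon_activity <- function(signature, regulons, n_perm = 1000L,
                             seed = 1L) {
  genes <- names(signature)
  N <- length(genes)
  rank_frac <- (N + 1 - rank(-signature, ties.method = "average")) / (N + 1)
  centered <- 2 * rank_frac - 1
  usable <- vapply(regulons, function(r) {
    sum(r$targets %in% genes) >= 3
  }, TRUE)
  if (any(!usable)) {
    warning(sprintf("%d regulon(s) with < 3 usable targets skipped",
                    sum(!usable)))
    regulons <- regulons[usable]
  }
  if (!length(regulons)) stop("no usable regulons")
  obs <- vapply(regulons, function(r) {
    keep <- r$targets %in% genes
    mean(r$modes[keep] * centered[r$targets[keep]])
  }, 0)
  sizes <- vapply(regulons, function(r) sum(r$targets %in% genes), 0L)
  null_by_size <- .with_seed(seed, {
    lapply(sort(unique(sizes)), function(m) {
      vapply(seq_len(n_perm), function(b) {
        mean(sample(c(-1, 1), m, replace = TRUE) *
               centered[sample.int(N, m)])
      }, 0)
    })
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))
  z <- p <- numeric(length(regulons))
  for (i in seq_along(regulons)) {
    null <- null_by_size[[as.character(sizes[i])]]
    z[i] <- (obs[i] - mean(null)) / stats::sd(null)
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  tab <- data.frame(tf = vapply(regulons, function(r) r$tf, ""),
                    n_targets = sizes, activity = obs, z = z, p = p,
                    q = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$z, tab$tf), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
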