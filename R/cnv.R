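#' Categorize CNV segment values into copy states
#'
#' Copy number is CN = 2^(Segment + 1) (Segment on the log2-ratio scale, so
#' CN is the diploid-scaled copy number). Categories: CN > 3.5 -> 2
#' (amplification); 2.5 < CN <= 3.5 -> 1 (single gain); CN < 0.5 -> -2
#' (double deletion); 0.5 <= CN < 1.5 -> -1 (single deletion); otherwise 0
#' (normal). Boundaries are exact: CN = 3.5 -> 1, CN = 2.5 -> 0,
#' CN = 1.5 -> 0, CN = 0.5 -> -1.
#'
#' @param segments genes x samples numeric matrix of segment values.
#' @return integer matrix of the same shape with entries in
#'   \{-2, -1, 0, 1, 2\}.
#' @export
segment_to_category <- function(segments) {
  stopifnot(is.matrix(segments))
  bad <- which(!is.finite(segments))
  if (length(bad)) {
    stop("non-finite segment values at cells: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  cn <- 2^(segments + 1)
  cat <- matrix(0L, nrow(segments), ncol(segments),
                dimnames = dimnames(segments))
  cat[cn > 3.5] <- 2L
  cat[cn > 2.5 & cn <= 3.5] <- 1L
  cat[cn < 0.5] <- -2L
  cat[cn >= 0.5 & cn < 1.5] <- -1L
  cat
}

#' CNV association tests per gene
#'
#' Two test families: (i) a chi-square test of the category x group (tumor /
#' normal) contingency table per gene — categories with zero total count are
#' dropped; when more than 20% of expected cells fall below 5 a Monte-Carlo
#' chi-square p (2000 resamples, seeded) replaces the asymptotic one; (ii) a
#' Kruskal-Wallis test of expression across observed category levels
#' (requires >= 2 levels each with >= 2 samples, NA otherwise). Both
#' families are BH-adjusted separately.
#'
#' @param categories genes x samples integer matrix from
#'   \code{\link{segment_to_category}}.
#' @param sample_groups named character vector ("tumor"/"normal" per
#'   sample).
#' @param expr optional genes x samples expression matrix (shared samples);
#'   when NULL the Kruskal-Wallis columns are NA.
#' @param mc_seed seed for the Monte-Carlo chi-square fallback.
#' @return data.frame gene, chi2_p, chi2_q, kw_p, kw_q.
#' @export
cnv_association_tests <- function(categories, sample_groups, expr = NULL,
                                  mc_seed = 1L) {
  stopifnot(is.matrix(categories))
  sample_groups <- sample_groups[colnames(categories)]
  if (anyNA(sample_groups)) stop("sample_groups must cover all samples")
  if (length(unique(sample_groups)) < 2) {
    warning("single sample group: chi-square group test skipped")
    chi2_p <- rep(NA_real_, nrow(categories))
  } else {
    chi2_p <- .with_seed(mc_seed, {
      apply(categories, 1, function(cats) {
        tab <- table(factor(cats), sample_groups)
        tab <- tab[rowSums(tab) > 0, , drop = FALSE]
        if (nrow(tab) < 2) return(1)
        exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        mc <- mean(exp_counts < 5) > 0.2
        suppressWarnings(
          stats::chisq.test(tab, simulate.p.value = mc, B = 2000)$p.value)
      })
    })
  }
  kw_p <- rep(NA_real_, nrow(categories))
  if (!is.null(expr)) {
    shared <- intersect(rownames(categories), rownames(expr))
    for (g in shared) {
      cats <- factor(categories[g, ])
      keep <- levels(cats)[table(cats) >= 2]
      if (length(keep) < 2) next
      sel <- cats %in% keep
      kw_p[match(g, rownames(categories))] <-
        stats::kruskal.test(expr[g, colnames(categories)][sel],
                            droplevels(cats[sel]))$p.value
    }
  }
  data.frame(gene = rownames(categories),
             chi2_p = chi2_p, chi2_q = stats::p.adjust(chi2_p, "BH"),
             kw_p = kw_p, kw_q = stats::p.adjust(kw_p, "BH"),
             stringsAsFactors = FALSE)
}

#' Prevalence of the dominant CNV type per gene
#'
#' For each significant gene, the non-zero category with the largest count
#' among tumor samples (ties: larger |category| wins, then amplification
#' over deletion) and its fraction of all tumor samples. Genes with no
#' non-zero category get type "none" and fraction 0.
#'
#' @param categories genes x samples integer matrix.
#' @param significant_genes genes to report (subset of matrix rows).
#' @param sample_groups named "tumor"/"normal" labels; when NULL all samples
#'   count as tumor.
#' @return data.frame gene, dominant_type (character), fraction.
#' @export
cnv_prevalence <- function(categories, significant_genes,
                           sample_groups = NULL) {
  stopifnot(all(significant_genes %in% rownames(categories)))
  tumor_cols <- if (is.null(sample_groups)) colnames(categories) else {
    names(sample_groups)[sample_groups == "tumor"]
  }
  n_tumor <- length(tumor_cols)
  rows <- lapply(significant_genes, function(g) {
    cats <- categories[g, tumor_cols]
    counts <- table(factor(cats, levels = c(-2, -1, 1, 2)))
    if (all(counts == 0)) {
      return(data.frame(gene = g, dominant_type = "none", fraction = 0,
                        stringsAsFactors = FALSE))
    }
    lv <- as.integer(names(counts))
    ord <- order(-counts, -abs(lv), -lv)   # count, then |cat|, then amp > del
    best <- lv[ord[1]]
    data.frame(gene = g, dominant_type = as.character(best),
               fraction = as.numeric(counts[as.character(best)]) / n_tumor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mutation enrichment within a clinical stratum
#'
#' Hypergeometric over-representation of a gene's mutated samples within a
#' stratum: N = total samples, M = stratum size, n = mutated samples,
#' k = mutated samples in the stratum.
#'
#' @param mutations binary genes x samples matrix.
#' @param strata named per-sample stratum labels.
#' @param gene gene id to test.
#' @param stratum stratum label to test against.
#' @return list: counts (`contingency_counts`) and p (upper-tail).
#' @export
mutation_strata_enrichment <- function(mutations, strata, gene, stratum) {
  if (!gene %in% rownames(mutations)) stop("gene not in mutation matrix")
  strata <- strata[colnames(mutations)]
  if (!stratum %in% strata) stop("empty stratum: ", stratum)
  in_stratum <- strata == stratum
  mutated <- mutations[gene, ] == 1
  counts <- contingency_counts(N = ncol(mutations), M = sum(in_stratum),
                               n = sum(mutated),
                               k = sum(mutated & in_stratum))
  list(counts = counts, p = hypergeom_upper_tail(counts))
}

#' Gleason grade group from primary + secondary scores
#'
#' Grade Group 1 = Gleason 6 or less; 2 = 3 + 4 = 7; 3 = 4 + 3 = 7;
#' 4 = Gleason 8; 5 = Gleason 9-10.
#'
#' @param primary,secondary integer Gleason pattern scores.
#' @return integer grade group in 1..5 (NA if outside the table).
#' @export
gleason_grade_group <- function(primary, secondary) {
  total <- primary + secondary
  out <- rep(NA_integer_, length(total))
  out[total <= 6] <- 1L
  out[primary == 3 & secondary == 4] <- 2L
  out[primary == 4 & secondary == 3] <- 3L
  out[total == 8] <- 4L
  out[total >= 9 & total <= 10] <- 5L
  out
}

#' Extraprostatic/intraprostatic classification from T stage
#'
#' T3-T4 -> "extraprostatic"; T2 -> "intraprostatic"; others NA.
#'
#' @param t_stage character vector like "T2a", "T3", "T4".
#' @return character classification.
#' @export
t_stage_class <- function(t_stage) {
  major <- substr(toupper(t_stage), 1, 2)
  out <- rep(NA_character_, length(t_stage))
  out[major %in% c("T3", "T4")] <- "extraprostatic"
  out[major == "T2"] <- "intraprostatic"
  out
}
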