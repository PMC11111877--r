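# Independent oracles, kept free of the package's own code paths.

# hypergeometric pmf by direct binomial-coefficient ratio
enum_pmf <- function(N, M, n, k) {
  choose(M, k) * choose(N - M, n - k) / choose(N, n)
}

# upper tail by summing the enumerated pmf
enum_upper_tail <- function(N, M, n, k) {
  ks <- k:min(M, n)
  sum(enum_pmf(N, M, n, ks))
}

# Cohen's kappa from the raw 2x2 table
direct_kappa <- function(a, b, c, d) {
  N <- a + b + c + d
  po <- (a + d) / N
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  (po - pe) / (1 - pe)
}

# pairwise Jaccard of two gene sets
jaccard <- function(x, y) length(intersect(x, y)) / length(union(x, y))

# mean within-block and between-block Jaccard over a term list
block_jaccard <- function(terms, blocks) {
  m <- length(terms)
  within <- c(); between <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    jij <- jaccard(terms[[i]], terms[[j]])
    if (blocks[i] == blocks[j]) within <- c(within, jij)
    else between <- c(between, jij)
  }
  list(within = mean(within), between = mean(between))
}

# AUC of a score separating two groups (Mann-Whitney form)
auc_score <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small convenience world used across tests
tiny_world <- function(seed = 7, ...) {
  cfg <- sim_config(seed = seed, ...)
  w <- gen_universe_and_terms(cfg)
  c(w, list(config = cfg))
}
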