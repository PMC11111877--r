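#' Derive a sub-stage seed from a root seed
#'
#' A single integer seed drives the whole pipeline; each stage draws its own
#' seed deterministically from the root so stages are individually
#' reproducible. The result is kept strictly below 2^31.
#'
#' @param seed root integer seed.
#' @param stage integer stage offset (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(stage), length(stage) == 1L, stage >= 0)
  as.integer((abs(seed) * 1000003 + stage * 7919) %% 2147483587)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  max_idx <- (ai + bj) / 2
  if (max_idx == expected) return(if (nij == expected) 1 else 0)
  (nij - expected) / (max_idx - expected)
}

# internal: assert x is a character vector of unique non-empty ids
.check_ids <- function(x, what = "ids") {
  if (!is.character(x) || anyDuplicated(x) || any(!nzchar(x))) {
    stop(sprintf("%s must be unique non-empty character strings", what),
         call. = FALSE)
  }
  invisible(x)
}

# internal: run expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
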