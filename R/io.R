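#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then member genes. Regulon
#' files may carry signed modes as `gene:+1` / `gene:-1` suffixes; these are
#' parsed when \code{signed = TRUE}.
#'
#' @param path file path.
#' @param signed parse `gene:mode` suffixes into a numeric mode vector.
#' @return named list of character vectors (unsigned) or of lists with
#'   `targets` and `modes` (signed).
#' @export
read_gmt <- function(path, signed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    genes <- f[-(1:2)]
    if (!signed) return(genes)
    parts <- strsplit(genes, ":", fixed = TRUE)
    targets <- vapply(parts, `[`, "", 1L)
    modes <- vapply(parts, function(p) {
      if (length(p) < 2) 1 else as.numeric(p[2])
    }, 0)
    list(targets = targets, modes = modes)
  })
  names(out) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, "")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors, or (with modes) named list of
#'   lists with `targets` and `modes`.
#' @param path output path.
#' @param description description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets))
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    genes <- if (is.list(s)) {
      paste0(s$targets, ":", ifelse(s$modes >= 0, "+", ""), s$modes)
    } else s
    paste(c(names(sets)[i], desc[i], genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a gene universe (one gene id per line)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_universe <- function(path) {
  g <- readLines(path)
  g <- g[nzchar(g)]
  .check_ids(g, "universe genes")
  g
}

#' @rdname read_universe
#' @param genes character vector of unique gene ids.
#' @export
write_universe <- function(genes, path) {
  .check_ids(genes, "universe genes")
  writeLines(genes, path)
  invisible(path)
}

#' Read/write a genes-by-samples numeric matrix as TSV
#'
#' Header row holds sample ids; first column holds gene ids.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param mat numeric matrix with row and column names.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
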