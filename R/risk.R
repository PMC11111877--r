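#' Five-lncRNA survival risk model
#'
#' The fixed linear model applied by \code{\link{risk_score}}. The shipped
#' defaults are the published prostate-cancer prognostic model:
#' score = (-0.56041) x AC106881.1 + 0.81588 x PRRT3-AS1 +
#' 1.234135 x AC004148.2 + 0.511379 x AP000844.2 + 0.297335 x AL354710.2,
#' with high/low stratification threshold 0.8789252. The model is unit-blind:
#' coefficients apply to whatever expression units the caller supplies.
#'
#' @param covariates covariate (gene) names.
#' @param coefficients linear coefficients, one per covariate.
#' @param threshold risk-score cutoff; scores strictly above it are "high".
#' @return a `risk_model` object.
#' @export
risk_model <- function(covariates = c("AC106881.1", "PRRT3-AS1",
                                      "AC004148.2", "AP000844.2",
                                      "AL354710.2"),
                       coefficients = c(-0.56041, 0.81588, 1.234135,
                                        0.511379, 0.297335),
                       threshold = 0.8789252) {
  .check_ids(covariates, "covariate names")
  stopifnot(length(coefficients) == length(covariates))
  names(coefficients) <- covariates
  structure(list(covariates = covariates, coefficients = coefficients,
                 threshold = threshold), class = "risk_model")
}

#' Apply a linear risk model to covariate expression
#'
#' score = sum over covariates of coefficient x expression; stratum "high"
#' if score > threshold, else "low" (a score exactly at the threshold is
#' "low").
#'
#' @param expr samples x covariates matrix or data.frame holding every model
#'   covariate as a column.
#' @param model a \code{\link{risk_model}}.
#' @return data.frame sample, score, stratum.
#' @export
risk_score <- function(expr, model = risk_model()) {
  expr <- as.data.frame(expr, optional = TRUE)  # keep names like PRRT3-AS1
  missing <- setdiff(model$covariates, colnames(expr))
  if (length(missing)) {
    stop("missing model covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  score <- as.matrix(expr[, model$covariates, drop = FALSE]) %*%
    model$coefficients
  data.frame(sample = if (!is.null(rownames(expr))) rownames(expr) else
               as.character(seq_len(nrow(expr))),
             score = drop(score),
             stratum = ifelse(drop(score) > model$threshold, "high", "low"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harrell's concordance index
#'
#' The fraction of permissible sample pairs in which the higher-risk sample
#' fails earlier. A pair is permissible when the shorter observed time is an
#' event (the earlier sample's failure is observed before the other's
#' follow-up ends); pairs tied on time with both events are not
#' permissible. Tied scores contribute 0.5.
#'
#' @param scores per-sample risk scores.
#' @param time observed times (>= 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return C-index in [0, 1].
#' @export
concordance_index <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event),
            all(event %in% c(0, 1)), all(is.finite(time)), all(time >= 0))
  if (length(scores) < 2 || sum(event) < 1) {
    stop("need >= 2 samples with >= 1 event")
  }
  conc <- 0; perm <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # orient so a has the shorter time
      if (time[i] < time[j]) { a <- i; b <- j }
      else if (time[j] < time[i]) { a <- j; b <- i }
      else next                         # tied times: not permissible
      if (event[a] != 1) next           # earlier sample censored
      perm <- perm + 1
      if (scores[a] > scores[b]) conc <- conc + 1
      else if (scores[a] == scores[b]) conc <- conc + 0.5
    }
  }
  if (perm == 0) stop("no permissible pairs")
  conc / perm
}
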