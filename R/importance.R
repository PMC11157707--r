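## Rank-based variable importance. Default importances of different
## algorithms live on incomparable scales, so only their ranks are used:
## within each base model the 25 most important variables get rank scores
## 25..1 and everything beyond rank 25 gets 1; base models get weight scores
## 20..1 from their rank in the stacking layer; a variable's score is the
## weight-averaged rank score over the base models of its feature type,
## standardized to the type's maximum so the top variable of each type has
## relative importance exactly 1.

#' Weighted rank-score ledger from raw importances
#'
#' Core rank aggregation, usable on any collection of models: per model,
#' variables are ranked by default importance (rank scores `topN..1`, 1
#' beyond `topN`); each variable's weighted average score is
#' `sum(w_b * r_vb) / sum(w_b)` over the models containing it, and relative
#' importance standardizes by the maximum within the variable's feature
#' type.
#'
#' @param importances List of named numeric vectors (default variable
#'   importances, one per model).
#' @param weights Numeric model weight scores (same length).
#' @param types Character feature type per model (same length); models of
#'   the same type must share variables.
#' @param topN Variables per model receiving graded rank scores.
#' @return `data.frame(feature, type, score, relative)` sorted by type and
#'   decreasing score.
#' @export
rankImportanceLedger <- function(importances, weights,
                                 types = rep("all", length(importances)),
                                 topN = 25L) {
  stopifnot(length(importances) == length(weights),
            length(types) == length(weights))
  out <- list()
  for (type in unique(types)) {
    idx <- which(types == type)
    vars <- names(importances[[idx[1]]])
    num <- stats::setNames(rep(0, length(vars)), vars)
    den <- 0
    for (b in idx) {
      imp <- importances[[b]]
      if (is.null(names(imp)) || !setequal(names(imp), vars))
        stop("models of type ", type, " must share variable names")
      r <- rank(-imp[vars], ties.method = "first")
      score <- ifelse(r <= topN, topN + 1L - r, 1)
      num <- num + weights[b] * score
      den <- den + weights[b]
    }
    wavg <- num / den
    out[[type]] <- data.frame(feature = vars, type = type, score = wavg,
                              relative = wavg / max(wavg), row.names = NULL)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$type, -res$score), ]
  rownames(res) <- NULL
  res
}

## base-model weights 20..1: each base column's importance rank is averaged
## over the five stacked models, then ranked 1..20
.baseModelWeights <- function(model) {
  rk <- vapply(model@stackModels, function(s)
    rank(-s$importance, ties.method = "first"), numeric(20L))
  avg <- rowMeans(rk)
  20L + 1L - rank(avg, ties.method = "first")
}

#' Rank-based variable importance of a trained ensemble
#'
#' Applies [rankImportanceLedger()] to the 20 base models' default
#' importances, with weight scores 20..1 derived from each base model's
#' average importance rank across the five stacked models.
#'
#' @param model A [CfdnaEnsemble-class].
#' @param topN Variables per base model receiving graded rank scores
#'   (default 25).
#' @return `data.frame(feature, type, score, relative)`; within each feature
#'   type the top variable has relative importance 1.
#' @export
rankImportance <- function(model, topN = 25L) {
  imps <- lapply(model@baseModels, `[[`, "importance")
  if (any(vapply(imps, is.null, logical(1))))
    stop("every base model must carry a default importance")
  types <- vapply(model@baseModels, `[[`, character(1), "type")
  w <- .baseModelWeights(model)
  rankImportanceLedger(imps, w, types, topN = topN)
}
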