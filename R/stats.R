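#' Area under the ROC curve
#'
#' Exact Mann-Whitney rank formulation: the probability that a random
#' positive scores above a random negative, with ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  y <- as.logical(labels > 0 | labels == TRUE)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes required")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index decision threshold
#'
#' Scans midpoints between adjacent sorted unique scores and returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1
#' (predicting positive when score > threshold). Ties go to the lowest
#' threshold. With a single unique score the degenerate cut has J = 0 and
#' that score is returned.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/TRUE = positive); both classes required.
#' @return The threshold, with attribute `"youden"` carrying the achieved J.
#' @export
youdenThreshold <- function(scores, labels) {
  y <- as.logical(labels > 0 | labels == TRUE)
  if (!any(y) || all(y)) stop("both classes required")
  u <- sort(unique(scores))
  if (length(u) == 1L) return(structure(u, youden = 0))
  ## interior midpoints plus the two degenerate cuts (all/none positive)
  cand <- c(u[1] - (u[2] - u[1]) / 2, (u[-1] + u[-length(u)]) / 2,
            u[length(u)])
  j <- vapply(cand, function(th)
    mean(scores[y] > th) + mean(scores[!y] <= th) - 1, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1L]   # ties -> lowest threshold
  structure(cand[best], youden = j[best])
}

#' Per-feature two-group rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test per feature column, exactly as used for
#' differential profiling of cfDNA features between cancer and non-cancer
#' groups. No multiplicity adjustment is applied (raw p-values are
#' reported, matching a raw P < 0.05 significance line).
#'
#' @param features Sample x feature numeric matrix.
#' @param labels Binary labels (1/TRUE = cancer); each group needs >= 3
#'   samples.
#' @return `data.frame(feature, statistic, p_value)`.
#' @export
differentialProfile <- function(features, labels) {
  y <- as.logical(labels > 0 | labels == TRUE)
  if (sum(y) < 3L || sum(!y) < 3L)
    stop("each group needs at least 3 samples")
  features <- as.matrix(features)
  cn <- colnames(features)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(features)))
  res <- vapply(seq_len(ncol(features)), function(j) {
    v <- features[, j]
    ht <- suppressWarnings(stats::wilcox.test(v[y], v[!y]))
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  data.frame(feature = cn, statistic = res[1L, ],
             p_value = res[2L, ], row.names = NULL)
}
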